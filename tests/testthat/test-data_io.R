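test_that("count matrix TSV reader parses a hand-written file exactly", {
  path <- write_lines_tmp(c("gene\ts1\ts2", "ga\t1\t2", "GB\t0\t5", "GC\t10\t10"))
  cm <- read_count_matrix(path)
  expect_s3_class(cm, "count_matrix")
  expect_equal(cm$gene_ids, c("GA", "GB", "GC"))
  expect_equal(cm$sample_ids, c("s1", "s2"))
  expect_equal(unname(cm$counts), matrix(c(1L, 0L, 10L, 2L, 5L, 10L), ncol = 2))
})

test_that("count matrix readers reject invalid values instead of coercing", {
  neg <- write_lines_tmp(c("gene\ts1\ts2", "GA\t-1\t2", "GB\t0\t5"))
  expect_error(read_count_matrix(neg), "non-negative")
  dup <- write_lines_tmp(c("gene\ts1", "KRT16\t3", "KRT16\t4"))
  expect_error(read_count_matrix(dup), "duplicate gene")
  frac <- write_lines_tmp(c("gene\ts1", "GA\t1.5"))
  expect_error(read_count_matrix(frac), "integral")
  dup2 <- write_lines_tmp(c("gene\ts1", "krt16\t3", "KRT16\t4"))
  expect_error(read_count_matrix(dup2), "duplicate gene")
})

test_that("count matrix round-trips through both dialects", {
  cm <- make_test_counts()
  tsv <- tempfile(fileext = ".tsv")
  write_count_matrix(cm, tsv, "tsv")
  back <- read_count_matrix(tsv, "tsv")
  expect_equal(back$counts, cm$counts)

  dir <- tempfile(); dir.create(dir)
  mtx <- file.path(dir, "matrix.mtx")
  write_count_matrix(cm, mtx, "mtx")
  back2 <- read_count_matrix(mtx, "mtx")
  expect_equal(back2$counts, cm$counts)
})

test_that("sample metadata reader enforces the study's group labels", {
  rows <- c("sample_id\tgroup\tpatient_id",
            sprintf("S%02d\tspecimen\tP%d", 1:11, c(1:8, 1:3)),
            "C1\tcontrol\t", "C2\tcontrol\t")
  md <- read_sample_metadata(write_lines_tmp(rows))
  expect_equal(nrow(md), 13L)
  expect_equal(as.integer(table(md$group)[c("specimen", "control")]), c(11L, 2L))

  bad <- write_lines_tmp(c("sample_id\tgroup", "S1\tcase"))
  expect_error(read_sample_metadata(bad), "unknown group")
  expect_error(read_sample_metadata(write_lines_tmp(character())), "")
})

test_that("metadata join rejects samples unknown to the counts", {
  cm <- make_test_counts()
  md <- cm$metadata
  md$sample_id[1] <- "not_a_sample"
  expect_error(set_sample_metadata(cm, md), "missing from metadata")
  expect_error(differential_expression(count_matrix(cm$counts)), "no sample metadata")
})

test_that("drug-gene table reader validates and deduplicates", {
  path <- write_lines_tmp(c("agent,gene,direction",
                            "Retinoic acid,DSG1,downregulates",
                            "Retinoic acid,DSG1,downregulates"), ".csv")
  tab <- read_drug_gene_table(path)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$agent, "Retinoic acid")
  expect_equal(tab$gene, "DSG1")

  bad <- write_lines_tmp(c("agent,gene,direction", "drugX,KRT16,sideways"), ".csv")
  expect_error(read_drug_gene_table(bad), "unknown regulation direction")
})

test_that("packaged dysregulated-gene table matches the printed records", {
  t1 <- load_fixture_table1()
  expect_equal(nrow(t1), 20L)
  expect_equal(as.integer(table(t1$direction)[c("up", "down")]), c(10L, 10L))
  expect_equal(t1$gene[1], "CALML5")
  expect_equal(t1$fold_change[1], 7.09)
  expect_equal(t1$change_coefficient[1], 86.48)
  first_down <- t1[t1$direction == "down", ][1, ]
  expect_equal(first_down$gene, "C16ORF82")
  expect_equal(first_down$fold_change, -125487.85)
  expect_equal(first_down$change_coefficient, -444.63)
  # printed convention: sign pairs up, magnitudes exceed 1
  expect_true(all(sign(t1$fold_change) == sign(t1$change_coefficient)))
  expect_true(all(abs(t1$fold_change) > 1))
})

test_that("packaged drug-gene table carries the printed cells", {
  t2 <- load_fixture_table2()
  ia <- t2$interactions
  crabp2_up <- ia$agent[ia$gene == "CRABP2" & ia$direction == "upregulates"]
  expect_setequal(crabp2_up, c("Retinoic acid", "Gentamycin", "Valproic acid"))
  expect_equal(unname(t2$gene_status[c("DSG1", "ATM")]), c("up", "down"))
  expect_length(ia$agent[ia$gene == "CASP14" & ia$direction == "upregulates"], 0)
  # slash-separated retinoid cell split into one interaction per agent
  s100a7_up <- ia$agent[ia$gene == "S100A7" & ia$direction == "upregulates"]
  expect_true(all(c("Isotretinoin", "Alitretinoin", "Tretinoin",
                    "4-oxoretinoic acid") %in% s100a7_up))
  # checksum over the whole fixture: every printed cell entry, nothing else
  expect_equal(nrow(ia), 96L)
  per_gene <- table(ia$gene)
  expect_equal(as.integer(per_gene[c("CALML5", "S100A7", "KRT16", "DEFB4A", "KRT6B",
                                 "KRT14", "DSG1", "DEFB103A", "CASP14", "CRABP2",
                                 "C16ORF82", "C11ORF65", "DPEP1", "PRB3", "NPAT",
                                 "ATM", "CASP8")]),
               c(3L, 6L, 12L, 3L, 4L, 8L, 2L, 2L, 2L, 6L,
                 1L, 1L, 10L, 2L, 3L, 12L, 19L))
  expect_false(any(c("PRB4", "MTRNR2L8", "MTRNR2L12") %in% ia$gene))
  expect_length(t2$gene_status, 20L)
})

test_that("GMT reader parses, deduplicates members and rejects bad lines", {
  p <- write_lines_tmp(c("SETA\tdesc\tKRT16\tKRT14"), ".gmt")
  sets <- read_gene_sets_gmt(p)
  expect_length(sets, 1L)
  expect_equal(sets$SETA, c("KRT16", "KRT14"))

  dupm <- read_gene_sets_gmt(write_lines_tmp(c("S\td\tA\ta\tB"), ".gmt"))
  expect_equal(dupm$S, c("A", "B"))

  expect_error(read_gene_sets_gmt(
    write_lines_tmp(c("S\td\tA", "S\td\tB"), ".gmt")), "duplicate gene set")
  expect_error(read_gene_sets_gmt(write_lines_tmp("S\tdesc", ".gmt")),
               "fewer than 3 fields")
})
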