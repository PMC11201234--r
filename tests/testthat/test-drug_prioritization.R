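# brute-force oracle: literal scan over interaction rows, independent of the
# package's grouping logic
brute_count <- function(ia, labels, members, mode) {
  norm <- function(x) tolower(gsub("\\s+", " ", trimws(x)))
  agents <- norm(ia$agent)
  agents[agents == "gentamycin"] <- "gentamicin"
  hit <- agents %in% members
  covered <- function(side) {
    genes <- labels$gene[labels$direction == side]
    found <- character()
    for (i in which(hit)) {
      ok <- ia$gene[i] %in% genes &&
        (mode == "any" ||
           (side == "up" && ia$direction[i] == "downregulates") ||
           (side == "down" && ia$direction[i] == "upregulates"))
      if (ok) found <- union(found, ia$gene[i])
    }
    found
  }
  list(up = covered("up"), down = covered("down"))
}

retinoid_members <- c("tretinoin", "isotretinoin", "alitretinoin", "fenretinide",
                      "retinoic acid", "4-oxoretinoic acid")

fixture_labels <- function() {
  st <- load_fixture_table2()$gene_status
  data.frame(gene = names(st), direction = unname(st), stringsAsFactors = FALSE)
}

test_that("retinoid and valproic-acid tallies reproduce the published counts", {
  t2 <- load_fixture_table2()
  labels <- fixture_labels()
  ret <- count_regulated_genes(t2$interactions, labels, "retinoids", mode = "any")
  expect_equal(ret$up_count, 7L)
  expect_equal(ret$down_count, 2L)
  expect_setequal(ret$covered_genes$up,
                  c("CALML5", "S100A7", "KRT16", "DEFB4A", "KRT14", "DSG1", "CRABP2"))
  expect_setequal(ret$covered_genes$down, c("ATM", "CASP8"))

  vpa <- count_regulated_genes(t2$interactions, labels, "valproic acid", mode = "any")
  expect_equal(vpa$up_count, 3L)
  expect_equal(vpa$down_count, 5L)
  expect_setequal(vpa$covered_genes$up, c("CALML5", "DEFB103A", "CRABP2"))
  expect_setequal(vpa$covered_genes$down,
                  c("C16ORF82", "DPEP1", "NPAT", "ATM", "CASP8"))

  ranking <- rank_drugs(t2$interactions, labels, mode = "any")
  expect_lt(which(ranking$family == "retinoids"),
            which(ranking$family == "valproic acid"))
  expect_equal(ranking$total[ranking$family == "retinoids"], 9L)
  expect_equal(ranking$total[ranking$family == "valproic acid"], 8L)
})

test_that("favorable mode agrees with brute-force enumeration of the fixture", {
  t2 <- load_fixture_table2()
  labels <- fixture_labels()
  for (fam in list(c("retinoids", retinoid_members),
                   c("valproic acid", "valproic acid"),
                   c("gentamicin", "gentamicin"))) {
    for (mode in c("any", "favorable")) {
      got <- count_regulated_genes(t2$interactions, labels, fam[1], mode = mode)
      want <- brute_count(t2$interactions, labels, fam[-1], mode)
      expect_setequal(got$covered_genes$up, want$up)
      expect_setequal(got$covered_genes$down, want$down)
    }
  }
  # favorable retinoid coverage differs from any-direction coverage
  fav <- count_regulated_genes(t2$interactions, labels, "retinoids",
                               mode = "favorable")
  any_ <- count_regulated_genes(t2$interactions, labels, "retinoids", mode = "any")
  expect_lt(fav$up_count + fav$down_count, any_$up_count + any_$down_count)
})

test_that("edge cases: empty gene list, single interaction, empty result", {
  t2 <- load_fixture_table2()
  empty <- count_regulated_genes(
    t2$interactions, data.frame(gene = character(), direction = character()),
    "retinoids")
  expect_equal(empty$up_count + empty$down_count, 0L)

  one <- data.frame(agent = "drugX", gene = "KRT16", direction = "downregulates")
  lab <- data.frame(gene = "KRT16", direction = "up")
  for (mode in c("any", "favorable")) {
    r <- rank_drugs(one, lab, mode = mode)
    expect_equal(nrow(r), 1L)
    expect_equal(r$total, 1L)
  }
  expect_equal(nrow(rank_drugs(one, data.frame(gene = "ATM", direction = "down"))), 0L)
})

test_that("adding an interaction never decreases any family total", {
  set.seed(12)
  labels <- fixture_labels()
  ia <- load_fixture_table2()$interactions
  for (rep in 1:20) {
    extra <- data.frame(agent = sample(c("tretinoin", "novel drug", "Gentamycin"), 1),
                        gene = sample(labels$gene, 1),
                        direction = sample(c("downregulates", "upregulates"), 1))
    before <- rank_drugs(ia, labels, mode = "any")
    after <- rank_drugs(rbind(ia, extra), labels, mode = "any")
    shared <- intersect(before$family, after$family)
    expect_true(all(after$total[match(shared, after$family)] >=
                      before$total[match(shared, before$family)]))
    ia <- rbind(ia, extra)
  }
})

test_that("favorable counts never exceed any-direction counts", {
  t2 <- load_fixture_table2()
  labels <- fixture_labels()
  any_ <- rank_drugs(t2$interactions, labels, mode = "any")
  fav <- rank_drugs(t2$interactions, labels, mode = "favorable")
  for (f in fav$family) {
    expect_lte(fav$total[fav$family == f], any_$total[any_$family == f])
  }
})

test_that("family counting is invariant to merging same-family agent names", {
  t2 <- load_fixture_table2()
  labels <- fixture_labels()
  merged <- t2$interactions
  merged$agent[normalize_agent(merged$agent) %in% retinoid_members] <- "Tretinoin"
  a <- count_regulated_genes(t2$interactions, labels, "retinoids", mode = "any")
  b <- count_regulated_genes(merged, labels, "retinoids", mode = "any")
  expect_equal(a[c("up_count", "down_count")], b[c("up_count", "down_count")])
  # alias: Gentamycin and Gentamicin are one family
  fams <- agent_family(c("Gentamycin", "gentamicin", " GENTAMYCIN "))
  expect_true(all(fams == "gentamicin"))
})
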