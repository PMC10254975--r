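# tiny deterministic annotation: two genes, every region label, one shared
# (multi-gene) probe and one intergenic probe
tiny_annotation <- function() {
  regions <- setdiff(region_categories(), "Promoter")
  dplyr::bind_rows(
    tibble::tibble(probe = paste0("cgA", seq_along(regions)), chrom = "chr1",
                   pos = seq_along(regions), gene = "GA", region = regions),
    tibble::tibble(probe = paste0("cgB", seq_along(regions)), chrom = "chr1",
                   pos = 10 + seq_along(regions), gene = "GB",
                   region = regions),
    tibble::tibble(probe = "cgShared", chrom = "chr1", pos = 30,
                   gene = c("GA", "GB"), region = c("Body", "TSS200")),
    tibble::tibble(probe = "cgInter", chrom = "chr1", pos = 40,
                   gene = NA_character_, region = NA_character_)
  )
}

dmp_row <- function(probe, direction) {
  tibble::tibble(probe = probe, coef = ifelse(direction == "hypo", -0.02, 0.02),
                 p = 1e-10, direction = direction)
}

test_that("the Bonferroni threshold and strict inequality are applied", {
  ewas <- tibble::tibble(
    feature = paste0("cg", 1:100),
    coef = rep(c(-0.02, 0.02), 50),
    p = c(rep(1e-9, 7), 0.05 / 100, seq(0.01, 0.92, length.out = 92))
  )
  hits <- select_significant_dmps(ewas, n_tests = 100, alpha = 0.05)
  # the probe exactly at the threshold is excluded
  expect_equal(nrow(hits), 7)
  expect_setequal(hits$direction[hits$coef < 0], "hypo")
  expect_setequal(hits$direction[hits$coef > 0], "hyper")

  ewas$coef[1] <- 0
  expect_warning(hits0 <- select_significant_dmps(ewas, 100), "undefined")
  expect_equal(nrow(hits0), 6)
})

test_that("full coverage of regions and directions yields 16 non-empty sets", {
  ann <- tiny_annotation()
  regions <- setdiff(region_categories(), "Promoter")
  dmps <- dplyr::bind_rows(
    dmp_row(paste0("cgA", seq_along(regions)), "hypo"),
    dmp_row(paste0("cgB", seq_along(regions)), "hyper")
  )
  sets <- build_gene_sets(dmps, ann)
  expect_equal(nrow(sets), 16)
  expect_setequal(sets$set, paste(rep(region_categories(), each = 2),
                                  c("hypo", "hyper"), sep = "_"))
  expect_true(all(sets$n_genes > 0))
})

test_that("empty DMP input still yields the 16 (empty) sets", {
  sets <- build_gene_sets(dmp_row(character(0), character(0)),
                          tiny_annotation())
  expect_equal(nrow(sets), 16)
  expect_true(all(sets$n_genes == 0))
})

test_that("promoter sets are the union of their four constituent regions", {
  ann <- tiny_annotation()
  dmps <- dplyr::bind_rows(
    dmp_row(c("cgA1", "cgA3"), "hypo"),   # TSS1500 + 5UTR of GA
    dmp_row("cgB2", "hyper")              # TSS200 of GB
  )
  sets <- build_gene_sets(dmps, ann)
  get <- function(name) sets$members[[which(sets$set == name)]]
  for (dir in c("hypo", "hyper")) {
    promoter <- get(paste0("Promoter_", dir))
    for (r in c("TSS200", "TSS1500", "5UTR", "1stExon")) {
      expect_true(all(get(paste0(r, "_", dir)) %in% promoter))
    }
  }
  expect_setequal(get("Promoter_hypo"), "GA")
  expect_setequal(get("Promoter_hyper"), "GB")
})

test_that("multi-gene probes feed both genes; intergenic probes feed none", {
  ann <- tiny_annotation()
  sets <- build_gene_sets(dmp_row("cgShared", "hypo"), ann)
  get <- function(name) sets$members[[which(sets$set == name)]]
  expect_setequal(get("Body_hypo"), "GA")       # Body label for GA
  expect_setequal(get("TSS200_hypo"), "GB")     # TSS200 label for GB
  expect_setequal(get("Promoter_hypo"), "GB")

  sets2 <- build_gene_sets(dmp_row("cgInter", "hypo"), ann)
  expect_true(all(sets2$n_genes == 0))
})

test_that("excluded genes are removed from every set", {
  ann <- tiny_annotation()
  dmps <- dmp_row(c("cgA2", "cgShared"), "hypo")
  sets <- build_gene_sets(dmps, ann, exclude_genes = "GA")
  expect_false(any(vapply(sets$members, function(m) "GA" %in% m, logical(1))))
  expect_identical(attr(sets, "excluded"), "GA")
})

test_that("construction is pure and monotone in the DMP table", {
  ann <- tiny_annotation()
  regions <- setdiff(region_categories(), "Promoter")
  dmps <- dplyr::bind_rows(
    dmp_row(paste0("cgA", seq_along(regions)), "hypo"),
    dmp_row("cgShared", "hypo")
  )
  s1 <- build_gene_sets(dmps, ann)
  s2 <- build_gene_sets(dmps, ann)
  expect_identical(s1$members, s2$members)
  # dropping any single probe never adds a member to any set
  for (i in seq_len(nrow(dmps))) {
    s_sub <- build_gene_sets(dmps[-i, ], ann)
    for (j in seq_len(nrow(s1))) {
      expect_true(all(s_sub$members[[j]] %in% s1$members[[j]]))
    }
  }
  expect_error(build_gene_sets(dmp_row("cgMissing", "hypo"), ann),
               "absent from annotation")
})

test_that("gene sets round-trip through GMT", {
  ann <- tiny_annotation()
  regions <- setdiff(region_categories(), "Promoter")
  sets <- build_gene_sets(
    dplyr::bind_rows(dmp_row(paste0("cgA", 1:7), "hypo"),
                     dmp_row(paste0("cgB", 1:7), "hyper")),
    ann)
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_equal(nrow(back), 16)
  expect_identical(back$set, sets$set)
  expect_identical(back$members[back$set == "Body_hypo"][[1]],
                   sets$members[sets$set == "Body_hypo"][[1]])
  expect_identical(back$description[1], paste(sets$region[1],
                                              sets$direction[1], sep = "|"))
})
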