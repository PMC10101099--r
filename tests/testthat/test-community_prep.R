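make_depth_table <- function(depths, n_otus = 20, seed = 1) {
  set.seed(seed)
  m <- t(vapply(depths, function(d) {
    p <- stats::rgamma(n_otus, 1)
    stats::rmultinom(1, d, p)[, 1]
  }, numeric(n_otus)))
  dimnames(m) <- list(sprintf("S%d", seq_along(depths)),
                      sprintf("OTU_%02d", seq_len(n_otus)))
  otu_table(m)
}

test_that("the depth filter is a strict less-than rule", {
  tab <- make_depth_table(c(4999, 5000, 5118))
  out <- suppressMessages(filter_low_depth(tab, 5000))
  expect_equal(rownames(out), c("S2", "S3"))      # only the 4,999-read sample goes
  expect_identical(rownames(suppressMessages(filter_low_depth(tab, 0))),
                   rownames(tab))                 # min_reads = 0 is the identity
  expect_error(filter_low_depth(tab, 1e6), "all samples")
})

test_that("rarefaction hits the target depth exactly and reproducibly", {
  tab <- make_depth_table(c(5118, 6000, 8000))
  r <- rarefy(tab, 5118, seed = 1)
  expect_true(all(rowSums(r) == 5118))
  expect_identical(unclass(rarefy(tab, 5118, seed = 1)), unclass(r))
  # auto depth resolves to the minimum library size
  r_auto <- rarefy(tab, "auto", seed = 1)
  expect_true(all(rowSums(r_auto) == 5118))
  # a sample already at depth is returned unchanged
  expect_identical(unclass(r)["S1", ], unclass(tab)["S1", ])
  expect_error(rarefy(tab, 7000), "S1")
})

test_that("rarefying an already-rarefied table is the identity", {
  tab <- make_depth_table(c(3000, 3000, 3000), seed = 3)
  expect_identical(unclass(suppressWarnings(rarefy(tab, 3000, seed = 9))),
                   unclass(tab))
})

test_that("relative abundances divide by library size", {
  m <- matrix(c(2, 2), 1, 2, dimnames = list("S1", c("a", "b")))
  expect_equal(unname(relative_abundance(m)[1, ]), c(0.5, 0.5))
  m2 <- matrix(c(1, 0, 3), 1, 3, dimnames = list("S1", c("a", "b", "c")))
  expect_equal(unname(relative_abundance(m2)[1, ]), c(0.25, 0, 0.75))
  tab <- make_depth_table(c(100, 200), seed = 2)
  expect_equal(unname(rowSums(relative_abundance(tab))), c(1, 1),
               tolerance = 1e-12)
  m3 <- matrix(c(1, 0), 2, 1, dimnames = list(c("S1", "S2"), "a"))
  expect_error(relative_abundance(m3), "all-zero")
})

core_test_table <- function(abund_prop, weeks = 10, depth = 10000) {
  # one focal OTU at a fixed proportion, the rest filler
  m <- cbind(focal = round(abund_prop * depth),
             filler = depth - round(abund_prop * depth))
  rownames(m) <- sprintf("S%02d", seq_len(weeks))
  meta <- study_metadata(data.frame(
    sample_id = rownames(m), participant_id = "P1", week = seq_len(weeks),
    smoking = "nonsmoker", health = "healthy", sex = "female", age = 30))
  list(tab = otu_table(m), meta = meta)
}

test_that("core membership follows detection and the prevalence ceiling rule", {
  # 0.002 in all 10 samples: in core at detection 0.001 / prevalence 0.85
  f <- core_test_table(rep(0.002, 10))
  cs <- core_microbiota(f$tab, f$meta, "P1", 0.001, 0.85)
  expect_true("focal" %in% cs$core_otu_ids)

  # 0.0005 everywhere: below detection, excluded
  f2 <- core_test_table(rep(5e-4, 10))
  cs2 <- core_microbiota(f2$tab, f2$meta, "P1", 0.001, 0.85)
  expect_false("focal" %in% cs2$core_otu_ids)

  # detected in 8 of 10 samples: 8 < ceiling(0.85 * 10) = 9, excluded
  f3 <- core_test_table(c(rep(0.01, 8), rep(5e-4, 2)))
  cs3 <- core_microbiota(f3$tab, f3$meta, "P1", 0.001, 0.85)
  expect_false("focal" %in% cs3$core_otu_ids)

  # abundances stay fractions of the whole sample and rows follow week order
  expect_true(all(cs$abundances >= 0 & cs$abundances <= 1))
  expect_equal(cs$weeks, 1:10)
})

test_that("core membership is monotone in detection and prevalence", {
  fx <- make_study_fixture(2, 12, seed = 13)
  for (pid in c("P01", "P02")) {
    base <- core_microbiota(fx$table, fx$metadata, pid, 0.001, 0.85)
    for (det in c(0.005, 0.02)) {
      up <- tryCatch(core_microbiota(fx$table, fx$metadata, pid, det, 0.85),
                     error = function(e) NULL)
      if (!is.null(up))
        expect_true(all(up$core_otu_ids %in% base$core_otu_ids))
    }
    for (prev in c(0.92, 1)) {
      up <- tryCatch(core_microbiota(fx$table, fx$metadata, pid, 0.001, prev),
                     error = function(e) NULL)
      if (!is.null(up))
        expect_true(all(up$core_otu_ids %in% base$core_otu_ids))
    }
  }
})

test_that("an empty core raises a helpful error", {
  f <- core_test_table(rep(5e-4, 10))
  expect_error(core_microbiota(f$tab, f$meta, "P1",
                               detection = 0.9999, prevalence = 1),
               "relaxing")
})
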