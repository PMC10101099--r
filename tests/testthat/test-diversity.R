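test_that("Hill numbers match closed forms and vegan's Renyi profile", {
  expect_equal(hill_number(rep(0.25, 4), 0), 4)
  expect_equal(hill_number(rep(0.25, 4), 1), 4)
  expect_equal(hill_number(rep(0.25, 4), 2), 4)
  expect_equal(hill_number(1, 0), 1)
  expect_equal(hill_number(1, 2), 1)
  expect_equal(hill_number(c(0.9, 0.1), 2), 1 / 0.82, tolerance = 1e-12)
  expect_error(hill_number(numeric(0), 1), "positive")
  expect_error(hill_number(c(0.5, 0.4), 1), "sum to 1")

  set.seed(10)
  p <- stats::rgamma(12, 0.5); p <- p / sum(p)
  ref <- vegan::renyi(p, scales = c(0, 1, 2), hill = TRUE)
  expect_equal(hill_number(p, 0), unname(ref[1]), tolerance = 1e-10)
  expect_equal(hill_number(p, 1), unname(ref[2]), tolerance = 1e-10)
  expect_equal(hill_number(p, 2), unname(ref[3]), tolerance = 1e-10)
})

test_that("Hill numbers are non-increasing in q on random communities", {
  set.seed(77)
  for (i in 1:20) {
    p <- stats::rgamma(sample(3:30, 1), 0.4); p <- p / sum(p)
    h <- vapply(c(0, 0.5, 1, 1.5, 2), function(q) hill_number(p, q), numeric(1))
    expect_true(all(diff(h) <= 1e-9))
  }
})

test_that("dissimilarity metrics satisfy their definitions and bounds", {
  m <- matrix(c(2, 2, 1, 3), 2, 2, byrow = TRUE,
              dimnames = list(c("X", "Y"), c("a", "b")))
  d <- dissimilarity(otu_table(m), "bray_curtis")
  expect_equal(d["X", "Y"], 2 / 8)                 # hand evaluation

  # identical samples: 0 for every metric
  m2 <- matrix(c(3, 5, 3, 5), 2, 2, byrow = TRUE,
               dimnames = list(c("X", "Y"), c("a", "b")))
  star <- ape::read.tree(text = "(a:1,b:1);")
  for (met in c("bray_curtis", "hellinger", "unifrac_unweighted",
                "unifrac_weighted"))
    expect_equal(dissimilarity(otu_table(m2), met, tree = star)["X", "Y"], 0)

  # hellinger = euclidean distance between sqrt-proportion vectors
  dh <- dissimilarity(otu_table(m), "hellinger")
  ph <- sqrt(m / rowSums(m))
  expect_equal(dh["X", "Y"], sqrt(sum((ph[1, ] - ph[2, ])^2)), tolerance = 1e-12)
  expect_lte(max(dh), sqrt(2) + 1e-12)

  # disjoint supports on a star tree: unweighted unifrac = 1
  m3 <- matrix(c(4, 0, 0, 7), 2, 2, byrow = TRUE,
               dimnames = list(c("X", "Y"), c("a", "b")))
  expect_equal(dissimilarity(otu_table(m3), "unifrac_unweighted",
                             tree = star)["X", "Y"], 1)
  expect_error(dissimilarity(otu_table(m3), "unifrac_unweighted"), "tree")
})

test_that("UniFrac agrees with a brute-force per-branch oracle on 5-leaf trees", {
  set.seed(42)
  for (rep in 1:6) {
    tree <- ape::rtree(5, tip.label = sprintf("t%d", 1:5))
    m <- matrix(stats::rpois(4 * 5, 3), 4, 5,
                dimnames = list(sprintf("S%d", 1:4), tree$tip.label))
    m[1, ] <- m[1, ] + 1                         # ensure no empty sample
    m[2, 1:2] <- 0; m[2, 3] <- m[2, 3] + 1       # partial support
    m[3, ] <- m[3, ] + 1
    m[4, 4:5] <- 0; m[4, 1] <- m[4, 1] + 1
    tab <- otu_table(m)
    for (weighted in c(FALSE, TRUE)) {
      met <- if (weighted) "unifrac_weighted" else "unifrac_unweighted"
      d <- dissimilarity(tab, met, tree = tree)
      for (i in 1:3) for (j in (i + 1):4) {
        expect_equal(d[i, j],
                     brute_unifrac(m[i, ], m[j, ], tree, weighted),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("weighted UniFrac on a unit star tree equals Bray-Curtis on proportions", {
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  set.seed(5)
  m <- matrix(stats::rpois(3 * 4, 20) + 1, 3, 4,
              dimnames = list(sprintf("S%d", 1:3), c("a", "b", "c", "d")))
  tab <- otu_table(m)
  wu <- dissimilarity(tab, "unifrac_weighted", tree = star)
  prop <- relative_abundance(tab)
  bc <- as.matrix(vegan::vegdist(prop, "bray"))
  expect_equal(unname(wu), unname(bc), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("LCBD performs Gower centring and normalizes to 1", {
  # hand-checked 3-sample case: D(1,2) = D(1,3) = 1, D(2,3) = 0
  d <- matrix(c(0, 1, 1, 1, 0, 0, 1, 0, 0), 3, 3,
              dimnames = list(paste0("S", 1:3), paste0("S", 1:3)))
  expect_equal(unname(lcbd(d)), c(2/3, 1/6, 1/6), tolerance = 1e-12)

  set.seed(9)
  for (i in 1:5) {
    tab <- random_counts_table(sample(4:12, 1), 8, seed = i)
    l <- lcbd(dissimilarity(tab, "hellinger"))
    expect_equal(sum(l), 1, tolerance = 1e-10)
  }

  # duplicated samples share the same LCBD
  m <- rbind(A = c(5, 1, 0), B = c(5, 1, 0), C = c(0, 3, 9))
  colnames(m) <- c("x", "y", "z")
  l <- lcbd(dissimilarity(otu_table(m), "bray_curtis"))
  expect_equal(l[["A"]], l[["B"]], tolerance = 1e-12)

  same <- matrix(1, 3, 3, dimnames = list(paste0("S", 1:3), paste0("O", 1:3)))
  expect_error(lcbd(dissimilarity(otu_table(same), "bray_curtis")),
               "no beta diversity")
})

test_that("SES matches exhaustive richness-null enumeration on a 4-leaf tree", {
  tree <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1):2);")
  m <- matrix(c(5, 3, 0, 0), 1, 4, dimnames = list("S1", c("A", "B", "C", "D")))
  res <- ses_phylo(otu_table(m), tree, n_null = 20000, top_k = 4, seed = 1)

  # oracle: all C(4,2) equally likely subsets; population moments
  D <- stats::cophenetic(tree)
  subs <- utils::combn(4, 2, simplify = FALSE)
  null_mpd <- vapply(subs, function(s) D[s[1], s[2]], numeric(1))
  mu <- mean(null_mpd)
  sigma <- sqrt(mean((null_mpd - mu)^2))
  ses_exact <- (D["A", "B"] - mu) / sigma

  got <- res[res$metric == "MPD", ]
  expect_equal(got$observed, D["A", "B"], ignore_attr = TRUE)
  expect_equal(got$null_mean, mu, tolerance = 0.05)
  expect_equal(got$ses, ses_exact, tolerance = 0.05)
  expect_equal(got$index_value, -got$ses)
  # for 2-leaf samples MNTD equals MPD
  expect_equal(res$ses[res$metric == "MNTD"], got$ses)
})

test_that("observed MPD/MNTD agree with picante on a larger community", {
  skip_if_not_installed("picante")
  set.seed(31)
  tree <- ape::rtree(12)
  m <- matrix(rbinom(3 * 12, 1, 0.6) * stats::rpois(3 * 12, 5), 3, 12,
              dimnames = list(sprintf("S%d", 1:3), tree$tip.label))
  m[rowSums(m > 0) < 2, 1:2] <- 1
  res <- ses_phylo(otu_table(m), tree, n_null = 9, top_k = 12, seed = 1)
  D <- stats::cophenetic(tree)
  ref_mpd <- picante::mpd(1 * (m > 0), D)
  ref_mntd <- picante::mntd(1 * (m > 0), D)
  expect_equal(res$observed[res$metric == "MPD"], ref_mpd, tolerance = 1e-10)
  expect_equal(res$observed[res$metric == "MNTD"], ref_mntd, tolerance = 1e-10)
})

test_that("degenerate nulls are flagged, not fabricated", {
  tree <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1):2);")
  # sample containing the entire pool: every null draw is identical
  m <- matrix(1, 1, 4, dimnames = list("S1", c("A", "B", "C", "D")))
  expect_warning(res <- ses_phylo(otu_table(m), tree, n_null = 99, top_k = 4,
                                  seed = 1), "degenerate null")
  expect_true(all(is.na(res$ses)))

  # star tree with equal branch lengths: all pairwise distances equal
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  m2 <- matrix(c(1, 1, 0, 0), 1, 4, dimnames = list("S1", c("A", "B", "C", "D")))
  expect_warning(res2 <- ses_phylo(otu_table(m2), star, n_null = 99, top_k = 4,
                                   seed = 1), "degenerate null")
  expect_true(all(is.na(res2$index_value)))
})

test_that("the abundance pool ranks by total count with lexicographic ties", {
  tree <- ape::rtree(6, tip.label = sprintf("O%d", 1:6))
  m <- matrix(c(9, 9, 5, 5, 1, 1), 2, 6, byrow = FALSE,
              dimnames = list(c("S1", "S2"), sprintf("O%d", c(3, 1, 2, 6, 5, 4))))
  m <- m[, sprintf("O%d", 1:6)]
  res <- suppressWarnings(
    ses_phylo(otu_table(m + 1), tree, n_null = 9, top_k = 3, seed = 1))
  expect_true(all(!is.na(res$observed)))
})
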