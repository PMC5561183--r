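test_that("extraction fills slots by distance within the window", {
  loci <- rbind(
    make_locus("focal", 10000, 11000, "+", "pF"),
    make_locus("up1", 8000, 9000, "+", "pU1"),
    make_locus("down1", 12000, 13000, "+", "pD1"),
    make_locus("far", 30000, 31000, "+", "pFar"),       # beyond 10 kb
    make_locus("other_contig", 10000, 11000, "+", "pX", contig = "c9")
  )
  arch <- c(pF = "MCE", pU1 = "ABC_tran", pD1 = "DUF330", pFar = "X",
            pX = "Y")
  nb <- extract_neighbourhood(loci, "focal", arch, focal_type = "I")
  expect_equal(unname(nb$slots["-1"]), "ABC_tran")
  expect_equal(unname(nb$slots["+1"]), "DUF330")
  expect_true(all(is.na(nb$slots[!names(nb$slots) %in% c("-1", "+1")])))
})

test_that("minus-strand focal genes get their sides swapped", {
  loci <- rbind(
    make_locus("focal", 10000, 11000, "-", "pF"),
    make_locus("left", 8000, 9000, "-", "pL"),
    make_locus("right", 12000, 13000, "-", "pR")
  )
  arch <- c(pF = "MCE", pL = "LEFTDOM", pR = "RIGHTDOM")
  nb <- extract_neighbourhood(loci, "focal", arch)
  expect_equal(unname(nb$slots["-1"]), "RIGHTDOM")
  expect_equal(unname(nb$slots["+1"]), "LEFTDOM")
})

test_that("at most max_genes slots fill per side, nearest first", {
  ups <- rbindlist(lapply(1:12, function(k) {
    make_locus(sprintf("up%02d", k), 50000 - k * 700, 50000 - k * 700 + 400,
               "+", sprintf("pu%02d", k))
  }))
  loci <- rbind(make_locus("focal", 50000, 51000, "+", "pF"), ups)
  arch <- setNames(sprintf("D%02d", 1:12), sprintf("pu%02d", 1:12))
  arch["pF"] <- "MCE"
  nb <- extract_neighbourhood(loci, "focal", arch)
  expect_equal(unname(nb$slots[paste0("-", 1:10)]), sprintf("D%02d", 1:10))
  expect_true(all(is.na(nb$slots[paste0("+", 1:10)])))
})

test_that("genes without a protein or architecture become NONE", {
  loci <- rbind(
    make_locus("focal", 10000, 11000, "+", "pF"),
    make_locus("rna", 8000, 9000, "+", NA_character_),
    make_locus("unknown", 12000, 13000, "+", "pNoArch")
  )
  nb <- extract_neighbourhood(loci, "focal", c(pF = "MCE"))
  expect_equal(unname(nb$slots[c("-1", "+1")]), c("NONE", "NONE"))
})

test_that("a missing focal gene is an error", {
  expect_error(
    extract_neighbourhood(make_locus("g1", 1, 10), "ghost", c()),
    "ghost", class = "mcetools_error")
})

test_that("similarity: identity, disjoint, and the hand-computed 0.8 case", {
  w <- neighbourhood_weights(0.5)
  a <- make_neighbourhood("a", c("-1" = "X", "+1" = "Y", "+2" = "Z"))
  expect_equal(neighbourhood_similarity(a, a, w), 1.0)
  b <- make_neighbourhood("b", c("-1" = "P", "+1" = "Q", "+2" = "R"))
  expect_equal(neighbourhood_similarity(a, b, w), 0.0)
  ## matches at +-1, mismatch at +2, everything else absent:
  ## S = (1 + 1) / (1 + 1 + 0.5) = 0.8
  c1 <- make_neighbourhood("c1", c("-1" = "X", "+1" = "Y", "+2" = "Z"))
  c2 <- make_neighbourhood("c2", c("-1" = "X", "+1" = "Y", "+2" = "W"))
  expect_equal(neighbourhood_similarity(c1, c2, w), 0.8)
  expect_equal(neighbourhood_similarity(c2, c1, w), 0.8)  # symmetric
})

test_that("present-vs-absent counts as mismatch; NONE matches NONE", {
  w <- neighbourhood_weights(0.5)
  a <- make_neighbourhood("a", c("-1" = "X", "+1" = "NONE"))
  b <- make_neighbourhood("b", c("+1" = "NONE"))
  ## occupied slots: -1 (mismatch present/absent, w=1), +1 (match, w=1)
  expect_equal(neighbourhood_similarity(a, b, w), 0.5)
})

test_that("weights decay and corruption near the centre hurts most", {
  w <- neighbourhood_weights(0.5)
  expect_equal(unname(w$w[c("-1", "+1")]), c(1, 1))
  expect_true(all(diff(w$w[paste0("+", 1:10)]) < 0))
  withr::local_seed(31)
  for (i in 1:40) {
    slots <- setNames(sprintf("D%d", sample.int(50L, 20L, replace = TRUE)),
                      c(paste0("-", 10:1), paste0("+", 1:10)))
    base <- make_neighbourhood("x", slots)
    corrupt <- function(slot) {
      s2 <- slots
      s2[slot] <- "CORRUPTED"
      make_neighbourhood("y", s2)
    }
    k <- sample(2:10, 1L)
    s_near <- neighbourhood_similarity(base, corrupt("+1"), w)
    s_far <- neighbourhood_similarity(base, corrupt(paste0("+", k)), w)
    expect_lte(s_near, s_far)
  }
})

test_that("non-normalized inputs are rejected", {
  a <- make_neighbourhood("a", c("-1" = "X"))
  b <- make_neighbourhood("b", c("-1" = "X"))
  b$orientation_normalized <- FALSE
  expect_error(neighbourhood_similarity(a, b), "normalized",
               class = "mcetools_error")
})

test_that("clustering merges identical neighbourhoods and stops below tau", {
  w <- neighbourhood_weights(0.5)
  a <- make_neighbourhood("a", c("-1" = "X", "+1" = "Y"))
  b <- make_neighbourhood("b", c("-1" = "X", "+1" = "Y"))
  cl <- cluster_neighbourhoods(list(a, b), w, tau = 0.5)
  expect_equal(nrow(cl$merges), 1L)
  expect_equal(cl$merges$similarity, 1.0)
  expect_equal(unique(cl$assignments$cluster), "a")
  ## all-zero similarities: no merges
  c1 <- make_neighbourhood("c", c("-1" = "P"))
  cl0 <- cluster_neighbourhoods(list(a, c1), w, tau = 0.5)
  expect_equal(nrow(cl0$merges), 0L)
  expect_equal(sort(cl0$assignments$cluster), c("a", "c"))
  expect_error(cluster_neighbourhoods(list(a), w, tau = 1.5),
               class = "mcetools_config_error")
  expect_error(cluster_neighbourhoods(list(), w),
               class = "mcetools_error")
})

test_that("merge similarities along the trace are non-increasing", {
  withr::local_seed(17)
  vocab <- c("A", "B", "C", "NONE")
  nbs <- lapply(1:12, function(i) {
    k <- sample(2:6, 1L)
    slots <- setNames(sample(vocab, k, replace = TRUE),
                      sample(c(paste0("-", 1:5), paste0("+", 1:5)), k))
    make_neighbourhood(sprintf("n%02d", i), slots)
  })
  cl <- cluster_neighbourhoods(nbs, neighbourhood_weights(0.5), tau = 0.1)
  if (nrow(cl$merges) > 1L) {
    expect_true(all(diff(cl$merges$similarity) <= 1e-12))
  }
  expect_true(all(cl$merges$similarity >= 0.1))
})

test_that("planted three-class sets recover exactly three clusters", {
  withr::local_seed(53)
  templates <- list(
    c("-2" = "ABC_tran", "-1" = "MlaE", "+1" = "DUF330"),
    c("-1" = "PqiA, PqiA", "+1" = "DUF330", "+2" = "Tol"),
    c("-1" = "NDUFA12", "-2" = "Sigma54", "+1" = "STAS")
  )
  nbs <- list(); truth <- character()
  for (cls in 1:3) {
    for (i in 1:6) {
      slots <- templates[[cls]]
      ## one far, low-weight slot of noise per neighbourhood
      slots[sprintf("+%d", sample(6:10, 1L))] <- sprintf("NOISE%d", i)
      nbs[[length(nbs) + 1L]] <-
        make_neighbourhood(sprintf("cl%d_n%d", cls, i), slots)
      truth <- c(truth, as.character(cls))
    }
  }
  cl <- cluster_neighbourhoods(nbs, neighbourhood_weights(0.5), tau = 0.5)
  got <- cl$assignments[match(vapply(nbs, `[[`, "", "focal_gene"),
                              focal_gene), cluster]
  expect_equal(uniqueN(got), 3L)
  expect_equal(adjusted_rand_index(got, truth), 1.0)
})

test_that("summaries report consensus patterns and conserved percentages", {
  w <- neighbourhood_weights(0.5)
  nbs <- c(
    lapply(1:5, function(i) make_neighbourhood(
      sprintf("a%d", i), c("-1" = "X", "+1" = "Y"))),
    lapply(1:5, function(i) make_neighbourhood(
      sprintf("b%d", i), c("-1" = "P", "+1" = "Q")))
  )
  cl <- cluster_neighbourhoods(nbs, w, tau = 0.5)
  summ <- summarise_neighbourhoods(cl, nbs)
  expect_equal(nrow(summ), 2L)
  expect_equal(summ$percentage, c(50, 50))   # two equal clusters of 5 from 10
  expect_equal(sum(summ$percentage), 100)
  expect_equal(summ[cluster == "a1"][["-1"]], "X")
  ## single neighbourhood: one cluster at 100%
  single <- cluster_neighbourhoods(nbs[1], w, tau = 0.5)
  expect_equal(summarise_neighbourhoods(single, nbs[1])$percentage, 100)
  ## 59-of-100 arithmetic pattern
  expect_equal(100 * 59 / 100, 59)
})

test_that("flipping an entire contig leaves normalized neighbourhoods unchanged", {
  withr::local_seed(71)
  for (rep in 1:200) {
    n <- sample(4:12, 1L)
    starts <- cumsum(sample(500:2000, n, replace = TRUE))
    loci <- rbindlist(lapply(seq_len(n), function(i) {
      make_locus(sprintf("g%02d", i), starts[i], starts[i] + 400L,
                 sample(c("+", "-"), 1L), sprintf("p%02d", i))
    }))
    arch <- setNames(sprintf("D%02d", seq_len(n)), sprintf("p%02d", seq_len(n)))
    focal <- sprintf("g%02d", sample.int(n, 1L))
    ## reverse-complement the contig: flip coordinates and strands
    L <- max(loci$end) + 1000L
    flipped <- copy(loci)
    new_start <- L - flipped$end
    new_end <- L - flipped$start
    flipped[, `:=`(start = new_start, end = new_end,
                   strand = fifelse(strand == "+", "-", "+"))]
    nb1 <- extract_neighbourhood(loci, focal, arch)
    nb2 <- extract_neighbourhood(flipped, focal, arch)
    expect_identical(nb1$slots, nb2$slots)
  }
})
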