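test_that("filter_significant applies per-family and default thresholds", {
  tt <- threshold_table(c(MCE = 20), default_threshold = 30)
  hits <- rbind(
    make_hit("p", "MCE", bit_score = 25),       # above MCE's 20
    make_hit("p", "MCE", bit_score = 19.9),     # below
    make_hit("p", "DUF330", bit_score = 29.9),  # below default 30
    make_hit("p", "DUF330", bit_score = 30)     # at default (inclusive)
  )
  kept <- filter_significant(hits, tt)
  expect_equal(kept$bit_score, c(25, 30))
  expect_equal(nrow(filter_significant(hits[0], tt)), 0L)
})

test_that("resolve_clan_overlaps keeps the most significant same-clan hit", {
  hits <- rbind(
    make_hit("p", "DOM1", "CLA", 10, 60, bit_score = 30),
    make_hit("p", "DOM2", "CLA", 40, 90, bit_score = 20)
  )
  expect_equal(resolve_clan_overlaps(hits)$domain_name, "DOM1")
})

test_that("MCE hits survive same-clan overlaps in all cases", {
  mce_clan <- make_hit("p", "MCE", "CLA", 10, 90, bit_score = 15)
  other <- make_hit("p", "DOM1", "CLA", 40, 120, bit_score = 40)
  out <- resolve_clan_overlaps(rbind(mce_clan, other))
  expect_setequal(out$domain_name, c("MCE", "DOM1"))
  ## and symmetrically when the MCE hit scores higher
  out2 <- resolve_clan_overlaps(rbind(
    make_hit("p", "MCE", "CLA", 10, 90, bit_score = 60), other))
  expect_setequal(out2$domain_name, c("MCE", "DOM1"))
})

test_that("overlap chains resolve greedily by descending significance", {
  ## A(10-50, 10) / B(40-90, 50) / C(80-120, 30): only B survives
  chain <- rbind(
    make_hit("p", "A", "CLA", 10, 50, bit_score = 10),
    make_hit("p", "B", "CLA", 40, 90, bit_score = 50),
    make_hit("p", "C", "CLA", 80, 120, bit_score = 30)
  )
  expect_equal(resolve_clan_overlaps(chain)$domain_name, "B")
  expect_equal(oracle_resolve(chain)$domain_name, "B")
  ## A(60) / B(50) / C(40) with A-B and B-C overlapping but not A-C:
  ## B is removed by A, and C survives because it only overlapped B
  chain2 <- rbind(
    make_hit("p", "A", "CLA", 10, 50, bit_score = 60),
    make_hit("p", "B", "CLA", 40, 90, bit_score = 50),
    make_hit("p", "C", "CLA", 85, 120, bit_score = 40)
  )
  expect_equal(resolve_clan_overlaps(chain2)$domain_name, c("A", "C"))
  expect_equal(oracle_resolve(chain2)$domain_name, c("A", "C"))
})

test_that("clanless hits and different clans never conflict", {
  hits <- rbind(
    make_hit("p", "DOM1", NA, 10, 60, bit_score = 30),
    make_hit("p", "DOM2", NA, 40, 90, bit_score = 20),
    make_hit("p", "DOM3", "CLA", 50, 100, bit_score = 10),
    make_hit("p", "DOM4", "CLB", 60, 110, bit_score = 5)
  )
  expect_equal(nrow(resolve_clan_overlaps(hits)), 4L)
})

test_that("resolve_clan_overlaps rejects multi-protein input", {
  hits <- rbind(make_hit("p1"), make_hit("p2"))
  expect_error(resolve_clan_overlaps(hits), "one",
               class = "mcetools_error")
})

test_that("resolution matches the brute-force subset oracle on random hits", {
  withr::local_seed(4242)
  for (i in 1:250) {
    hits <- random_hits(sample(1:8, 1L))
    got <- resolve_clan_overlaps(hits)
    want <- oracle_resolve(hits)
    expect_equal(got[, .(domain_name, start, end, bit_score)],
                 want[, .(domain_name, start, end, bit_score)])
  }
})

test_that("architectures order by start and classify into the type scheme", {
  arch <- build_architecture(rbind(
    make_hit("p", "DUF3407", start = 100, end = 280, bit_score = 60),
    make_hit("p", "MCE", start = 5, end = 86, bit_score = 50)
  ))
  expect_equal(arch$domains, c("MCE", "DUF3407"))
  expect_equal(arch$type_label, "II")
  expect_equal(arch$mce_count, 1L)

  empty <- build_architecture(make_hit()[0], protein_id = "p0")
  expect_equal(empty$domains, character())
  expect_equal(empty$type_label, "non_mce")

  seven <- rbindlist(lapply(seq_len(7), function(k) {
    make_hit("p", "MCE", start = 1 + (k - 1) * 110, end = 81 + (k - 1) * 110)
  }))
  expect_equal(build_architecture(seven)$mce_count, 7L)
  expect_equal(build_architecture(seven)$type_label, "IV")
})

test_that("classify_type is total and matches the four-type scheme", {
  expect_equal(classify_type("MCE"), "I")
  expect_equal(classify_type(c("MCE", "DUF3407")), "II")
  expect_equal(classify_type(c("DUF3407", "MCE")), "other_mce")  # order matters
  expect_equal(classify_type(rep("MCE", 3)), "III")
  expect_equal(classify_type(rep("MCE", 7)), "IV")
  expect_equal(classify_type(rep("MCE", 2)), "other_mce")
  expect_equal(classify_type(c("MCE", "DOMX", "MCE", "MCE")), "other_mce")
  expect_equal(classify_type(c("DOMX", "DOMY")), "non_mce")
  expect_equal(classify_type(character()), "non_mce")
})

test_that("the final architecture is invariant to input hit order", {
  withr::local_seed(99)
  for (i in 1:50) {
    hits <- random_hits(sample(2:8, 1L))
    tt <- threshold_table(default_threshold = 20)
    base <- build_architectures(hits, thresholds = tt)
    shuffled <- build_architectures(hits[sample(.N)], thresholds = tt)
    expect_equal(shuffled, base)
  }
})

test_that("merge_synonyms canonicalises, passes unknowns, and is idempotent", {
  m <- default_synonym_map()
  expect_equal(merge_synonyms("ABC_tran, AAA_21", m), "ABC_tran")
  expect_equal(merge_synonyms("PqiA, PqiA", m), "PqiA, PqiA")
  once <- merge_synonyms(c("ABC_tran, AAA_21", "MCE"), m)
  expect_equal(merge_synonyms(once, m), once)
})

test_that("cyclic or chained synonym maps are a config error", {
  expect_error(validate_synonym_map(c(A = "B", B = "A")),
               class = "mcetools_config_error")
  expect_error(validate_synonym_map(c(A = "B", B = "C")),
               class = "mcetools_config_error")
  expect_silent(validate_synonym_map(c(A = "B", B = "B")))
})

test_that("build_architectures covers hitless proteins as non_mce", {
  proteins <- data.table(protein_id = c("pa", "pb"), genome_id = "g",
                         species_id = "s", phylum = "X",
                         superkingdom = "Bacteria", length = c(100L, 200L))
  archs <- build_architectures(make_hit("pa"), proteins)
  expect_equal(archs[protein_id == "pb", type_label], "non_mce")
  expect_equal(archs[protein_id == "pb", domains], "")
  expect_equal(archs[protein_id == "pa", type_label], "I")
})
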