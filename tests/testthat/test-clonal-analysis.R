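test_that("clones are keyed on V gene, J gene and CDRH3 with per-organ frequencies", {
  rec <- data.frame(
    sequence_id = c("s1", "s2"), mouse_id = "m1",
    organ = c("BM", "spleen"),
    v_call = c("IGHV1-1*01", "IGHV1-1*02"),  # same gene, different allele
    j_call = "IGHJ1", cdrh3_aa = "CARDYW", count = c(2L, 5L),
    stringsAsFactors = FALSE
  )
  cl <- assign_clones(rec)
  expect_equal(length(unique(cl$clone_key)), 1)
  expect_equal(nrow(cl), 2)  # one clone present in two organs

  rec$j_call <- c("IGHJ1", "IGHJ2")
  expect_equal(length(unique(assign_clones(rec)$clone_key)), 2)

  # counts 3,3,2,2 over two keys (3+2, 3+2) in one organ -> 0.5 / 0.5
  rec2 <- data.frame(
    sequence_id = sprintf("s%d", 1:4), mouse_id = "m1", organ = "BM",
    v_call = "IGHV1-1", j_call = "IGHJ1",
    cdrh3_aa = c("CARDYW", "CARDFW", "CARDYW", "CARDFW"),
    count = c(3L, 2L, 2L, 3L), stringsAsFactors = FALSE
  )
  cl2 <- assign_clones(rec2)
  expect_equal(nrow(cl2), 2)
  expect_equal(unname(cl2$frequency), c(0.5, 0.5))
  expect_error(assign_clones(rec2[0, ]), "no input")
})

test_that("clonotype linkage respects the strict identity threshold", {
  # length 6, 1 mismatch: identity 5/6 = 0.833 < 0.9 -> separate
  ct <- cluster_clonotypes(make_clone_table(
    "IGHV1-1", "IGHJ1", c("CARDYW", "CARDFW")), 0.9)
  expect_equal(length(unique(ct$clonotype_id)), 2)

  # length 12, 1 mismatch: identity 11/12 = 0.917 > 0.9 -> linked
  ct2 <- cluster_clonotypes(make_clone_table(
    "IGHV1-1", "IGHJ1", c("CARDYWDYWDYW", "CARDFWDYWDYW")), 0.9)
  expect_equal(length(unique(ct2$clonotype_id)), 1)

  # identical CDRH3, different V genes: never linked
  ct3 <- cluster_clonotypes(make_clone_table(
    c("IGHV1-1", "IGHV1-2"), "IGHJ1", c("CARDYWDYWDYW", "CARDYWDYWDYW")),
    0.5)
  expect_equal(length(unique(ct3$clonotype_id)), 2)

  # inclusive mode links identity exactly at the threshold
  # length 10, 1 mismatch: identity 0.9 exactly
  tbl <- make_clone_table("IGHV1-1", "IGHJ1", c("CARDYWDYWA", "CARDFWDYWA"))
  expect_equal(length(unique(
    cluster_clonotypes(tbl, 0.9, inclusive = FALSE)$clonotype_id)), 2)
  expect_equal(length(unique(
    cluster_clonotypes(tbl, 0.9, inclusive = TRUE)$clonotype_id)), 1)
})

test_that("clonotype clustering matches the brute-force single-linkage oracle", {
  set.seed(42)
  for (rep in 1:25) {
    inst <- random_clone_instance(sample(5:40, 1))
    tbl <- make_clone_table(inst$v_gene, inst$j_gene, inst$cdrh3_aa)
    ct <- cluster_clonotypes(tbl, 0.9)
    uq <- unique(as.data.frame(ct)[, c("clone_key", "v_gene", "j_gene",
                                       "cdrh3_aa", "clonotype_id")])
    uq <- uq[order(uq$clone_key, method = "radix"), ]
    oracle <- oracle_clonotypes(uq$v_gene, uq$j_gene, uq$cdrh3_aa, 0.9)
    expect_true(same_partition(uq$clonotype_id, oracle),
                label = paste("instance", rep))
  }
})

test_that("expansion profiles bin frequency-ranked clones deterministically", {
  # uniform 10-clone repertoire, bins 1-3 / 4-10
  p <- expansion_profile(rep(0.1, 10), c(3, 10))
  expect_equal(p$fraction, c(0.3, 0.7))
  # exhaustive single bin
  expect_equal(expansion_profile(c(0.5, 0.3, 0.2), 3)$fraction, 1.0)
  # hand-summed two-bin case
  p2 <- expansion_profile(c(0.4, 0.3, 0.2, 0.1), c(2, 4))
  expect_equal(p2$fraction, c(0.7, 0.3))
  # bins always partition all ranks
  p3 <- expansion_profile(c(0.4, 0.3, 0.2, 0.1), 2)
  expect_equal(sum(p3$fraction), 1)
  expect_equal(nrow(expansion_profile(numeric(0), 3)), 0)
})

test_that("Hill diversity matches closed forms and limits", {
  expect_equal(hill_diversity(rep(1 / 7, 7), c(0, 0.5, 1, 2, 10)),
               rep(7, 5))
  expect_equal(hill_diversity(c(0.75, 0.25), 2), 1.6)
  expect_equal(hill_diversity(c(0.5, 0.5), 1), 2)
  expect_equal(hill_diversity(c(0.2, 0.3, 0.5), 0), 3)
  expect_error(hill_diversity(c(0.5, 0.4), 1), "sum to 1")
  expect_error(hill_diversity(c(0.5, 0.5), -1), "non-negative")
})

test_that("Hill diversity is continuous across alpha = 1 and non-increasing in alpha", {
  set.seed(7)
  for (rep in 1:50) {
    f <- runif(sample(2:30, 1))
    f <- f / sum(f)
    expect_lt(abs(hill_diversity(f, 1 - 1e-6) - hill_diversity(f, 1)),
              1e-3)
    expect_lt(abs(hill_diversity(f, 1 + 1e-6) - hill_diversity(f, 1)),
              1e-3)
    grid <- hill_diversity(f, seq(0, 10, by = 0.25))
    expect_true(all(diff(grid) <= 1e-10))
  }
})

test_that("evenness profiles are 1 for uniform repertoires and bounded otherwise", {
  prof <- evenness_profile(rep(0.125, 8))
  expect_true(all(abs(prof$evenness - 1) < 1e-12))
  expect_equal(attr(prof, "species_richness"), 8)

  # ^0E = 1 always
  prof2 <- evenness_profile(c(0.7, 0.2, 0.1))
  expect_equal(prof2$evenness[prof2$alpha == 0], 1)
  expect_true(all(prof2$evenness > 0 & prof2$evenness <= 1))

  # single dominant clone: ^2E well below 1
  dom <- evenness_profile(c(0.999, 0.001), alpha_grid = c(0, 1, 2))
  expect_lt(dom$evenness[dom$alpha == 2], 0.51)
  # degenerate single clone
  expect_equal(shannon_evenness(1), 1)
})

test_that("SHM load is the masked mismatch fraction over the IGHV region", {
  a <- paste(rep("A", 312), collapse = "")
  expect_equal(shm_load(a, a), 0)

  b <- strsplit(a, "")[[1]]
  b[1:3] <- "C"
  expect_equal(shm_load(paste(b, collapse = ""), a, region_end = 300),
               0.01)

  # 1 mismatch + 10 N positions over 312 -> 1/302
  c1 <- strsplit(a, "")[[1]]
  c1[5] <- "G"
  c1[10:19] <- "N"
  expect_equal(shm_load(paste(c1, collapse = ""), a), 1 / 302)

  # only the first region_end positions count
  long <- paste(c(rep("A", 312), rep("C", 50)), collapse = "")
  expect_equal(shm_load(long, paste(rep("A", 362), collapse = "")), 0)
  expect_true(is.na(shm_load("NNNN", "ACGT")))
})
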