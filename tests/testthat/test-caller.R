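# helper: a reproducible degenerate-repeat reference with anchor
make_ref <- function(len = 300, seed = 101) {
  set.seed(seed)
  paste0("ACTCAGGTACCATCGAGGATCCTAACGCAT", sample_telomere(len - 30))
}

test_that("perfect identity is non-divergent over the full length", {
  ref <- make_ref(200)
  call <- call_divergence(align_clone(ref, ref))
  expect_false(call$diverged)
  expect_equal(call$undiverged_length_nt, 200)
  expect_identical(call$reason, "perfect")
  expect_true(is.na(call$divergence_point_1based))
})

test_that("indel tolerance boundary is bit-exact at 6 versus 7 nt", {
  ref <- make_ref(300)
  # insertion after reference position 100; content chosen to differ
  # from the downstream reference sequence immediately
  ins6 <- "ACACAC"
  ins7 <- "ACACACA"
  clone6 <- paste0(substr(ref, 1, 100), ins6, substr(ref, 101, 300))
  clone7 <- paste0(substr(ref, 1, 100), ins7, substr(ref, 101, 300))
  call6 <- call_divergence(align_clone(clone6, ref))
  call7 <- call_divergence(align_clone(clone7, ref))
  expect_false(call6$diverged)
  expect_identical(call6$reason, "tolerated_indel")
  expect_true(call7$diverged)
  expect_identical(call7$reason, "diverged_long_indel")
  expect_equal(call7$divergence_point_1based, 101)
  expect_equal(call7$undiverged_length_nt, 100)
  # deletions at the same boundary
  del6 <- paste0(substr(ref, 1, 100), substr(ref, 107, 300))
  del7 <- paste0(substr(ref, 1, 100), substr(ref, 108, 300))
  expect_false(call_divergence(align_clone(del6, ref))$diverged)
  call_d7 <- call_divergence(align_clone(del7, ref))
  expect_true(call_d7$diverged)
  # inside degenerate repeats a deletion's exact placement is ambiguous
  # up to the repeat phase, so the junction may slide a few nt distally
  expect_true(call_d7$divergence_point_1based >= 101 &&
                call_d7$divergence_point_1based <= 107)
})

test_that("an unalignable random tail is called at its first divergent base", {
  ref <- make_ref(300)
  set.seed(33)
  # random non-repeat tail, first base forced to differ from the
  # reference so the junction is exactly position 151
  tail_seq <- paste(sample(c("A", "C"), 150, TRUE), collapse = "")
  clone <- paste0(substr(ref, 1, 150), tail_seq)
  call <- call_divergence(align_clone(clone, ref))
  expect_true(call$diverged)
  expect_true(call$reason %in% c("diverged_unalignable_tail",
                                 "diverged_long_indel"))
  expect_equal(call$divergence_point_1based, 151)
  expect_equal(call$undiverged_length_nt, 150)
})

test_that("a fresh degenerate-repeat tail is localized at the junction", {
  ref <- make_ref(300)
  set.seed(34)
  hits <- 0L
  for (rep in 1:30) {
    b <- sample(80:250, 1)
    tail_seq <- sample_telomere(300 - b + 1)
    clone <- paste0(substr(ref, 1, b - 1), tail_seq)
    # effective junction: first base where the fresh tail differs
    eff <- b - 1 + which(utf8ToInt(tail_seq) !=
                           utf8ToInt(substr(ref, b, 300)))[1]
    call <- call_divergence(align_clone(clone, ref))
    if (call$diverged &&
        abs(call$divergence_point_1based - eff) <= 5) hits <- hits + 1L
  }
  expect_gte(hits, 28L)
})

test_that("isolated substitutions are tolerated without number cap", {
  ref <- make_ref(260)
  clone <- ref
  for (p in seq(40, 240, by = 20)) {   # 11 isolated point mutations
    orig <- substr(clone, p, p)
    substr(clone, p, p) <- if (orig == "G") "A" else "C"
  }
  call <- call_divergence(align_clone(clone, ref))
  expect_false(call$diverged)
  expect_identical(call$reason, "tolerated_substitutions")
})

test_that("truncation counting uses a strict 125-nt threshold", {
  calls <- data.frame(undiverged_length_nt = c(124, 125, 126))
  expect_equal(call_truncations(calls), 1L)
  expect_equal(call_truncations(
    data.frame(undiverged_length_nt = c(200, 300, 250))), 0L)
})

test_that("reference selection breaks ties lexicographically", {
  set.seed(55)
  s <- sample_telomere(150)
  set <- telomere_set("TEL06R", "s1", "wt", 30,
                      data.frame(clone_id = paste0("c", 6:1), bases = s))
  expect_identical(select_reference(set), "c1")
})

test_that("reference selection prefers the longest clone absent divergence", {
  ref <- make_ref(250)
  set <- telomere_set("TEL06R", "s1", "wt", 30,
                      data.frame(clone_id = c("a", "b"),
                                 bases = c(ref, substr(ref, 1, 240))))
  expect_identical(select_reference(set), "a")
})

test_that("a longest clone with a divergent tail is demoted by majority", {
  set.seed(56)
  shared <- make_ref(300)
  long_clone <- paste0(substr(shared, 1, 170),
                       sample_telomere(150))  # 320 nt, foreign distal 150
  clones <- data.frame(
    clone_id = c(paste0("c", 1:5), "z_long"),
    bases = c(rep(shared, 5), long_clone))
  set <- telomere_set("TEL06R", "s1", "wt", 30, clones)
  expect_identical(select_reference(set), "c1")
})

test_that("call_set output is sorted by undiverged length", {
  set.seed(57)
  cfg <- sim_config(seed = 77, divergence_rate = 0.02, clones_per_set = 25)
  sim <- emit_clone_set(cfg)
  calls <- call_set(sim$set)
  expect_equal(nrow(calls), 25)
  expect_true(all(diff(calls$undiverged_length_nt) <= 0))
  expect_true(calls$reference_id[1] %in% calls$clone_id)
  ref_row <- calls[calls$clone_id == calls$reference_id[1], ]
  expect_false(ref_row$diverged)
  expect_equal(ref_row$undiverged_length_nt, ref_row$clone_length_nt)
})

test_that("a pure shortening staircase yields only non-diverged calls", {
  ref <- make_ref(300)
  lens <- seq(300, 210, by = -3)
  clones <- data.frame(clone_id = sprintf("c%02d", seq_along(lens)),
                       bases = substring(ref, 1, lens))
  set <- telomere_set("TEL06R", "s1", "wt", 30, clones)
  calls <- call_set(set)
  expect_false(any(calls$diverged))
  expect_equal(sort(calls$undiverged_length_nt), sort(lens))
})

test_that("relaxing tolerance rules never increases diverged calls", {
  cfg <- sim_config(seed = 909, divergence_rate = 0.01, clones_per_set = 40)
  sim <- emit_clone_set(cfg)
  strict <- call_set(sim$set, divergence_rules(max_indel_nt = 3))
  default <- call_set(sim$set, divergence_rules())
  loose <- call_set(sim$set, divergence_rules(max_indel_nt = 12,
                                              max_substitution_run = 3))
  expect_gte(sum(strict$diverged), sum(default$diverged))
  expect_gte(sum(default$diverged), sum(loose$diverged))
})

test_that("calling requires at least two clones", {
  set <- telomere_set("TEL06R", "s1", "wt", 30,
                      data.frame(clone_id = "only", bases = "TGTGGTGG"))
  expect_error(select_reference(set), "at least 2")
})
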