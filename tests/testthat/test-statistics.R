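# Frequencies, co-occurrence, segments, bootstrap, Wu-Kabat, germline.

test_that("amino-acid frequencies are computed on unique residues", {
  f <- aa_frequencies(c("TYR", "TYR", "SER", "GLY"))
  expect_equal(unname(f["TYR"]), 50)
  expect_equal(unname(f["SER"]), 25)
  expect_equal(unname(f["GLY"]), 25)
  expect_equal(sum(f), 100, tolerance = 1e-6)
  expect_length(f, 20)
  expect_error(aa_frequencies(character(0)))
  expect_error(aa_frequencies("XYZ"), "nonstandard")
})

test_that("class frequencies partition the 20 amino acids", {
  expect_equal(unname(class_frequencies(aa_frequencies("SER"))["polar"]), 100)
  expect_equal(unname(class_frequencies(aa_frequencies("GLY"))["special"]), 100)
  set.seed(5)
  for (i in 1:10) {
    f <- aa_frequencies(sample(standard_aa(), 30, TRUE))
    cf <- class_frequencies(f)
    expect_equal(sum(cf), 100, tolerance = 1e-6)
    expect_named(cf, c("nonpolar", "polar", "positive", "negative", "special"))
  }
})

test_that("bootstrap CI is degenerate on constant data, reproducible on a seed", {
  ci <- group_mean_ci(rep(7, 12), n_boot = 200, seed = 1)
  expect_equal(ci$point, 7)
  expect_equal(ci$lo, 7)
  expect_equal(ci$hi, 7)

  vals <- rnorm(40, 10, 2)
  a <- group_mean_ci(vals, n_boot = 500, seed = 99)
  b <- group_mean_ci(vals, n_boot = 500, seed = 99)
  expect_identical(a, b)
  c2 <- group_mean_ci(vals, n_boot = 500, seed = 100)
  expect_false(identical(a$lo, c2$lo))
  expect_lte(a$lo, a$hi)
  expect_gte(a$lo, min(vals))
  expect_lte(a$hi, max(vals))
  # the default resample count
  expect_equal(formals(group_mean_ci)$n_boot, 5000)
})

test_that("bootstrapping leaves the caller's RNG stream untouched", {
  set.seed(123)
  vals <- rnorm(10)
  before <- .Random.seed
  invisible(group_mean_ci(vals, n_boot = 50, seed = 7))
  expect_identical(before, .Random.seed)
})

test_that("co-occurrence rows are contact-weighted and row-normalized", {
  ct <- data.frame(ab_aa = "TYR", ag_aa = "ALA", stringsAsFactors = FALSE)
  m <- cooccurrence_matrix(ct)
  expect_equal(dim(m), c(20, 20))
  expect_equal(m["TYR", "ALA"], 100)
  expect_equal(sum(m), 100)
  expect_setequal(attr(m, "empty_rows"), setdiff(standard_aa(), "TYR"))

  # random multinomial contact table vs an independent count-then-normalize
  set.seed(17)
  ct2 <- data.frame(ab_aa = sample(standard_aa(), 400, TRUE),
                    ag_aa = sample(standard_aa(), 400, TRUE),
                    stringsAsFactors = FALSE)
  m2 <- cooccurrence_matrix(ct2)
  want <- table(factor(ct2$ab_aa, standard_aa()),
                factor(ct2$ag_aa, standard_aa()))
  want <- 100 * sweep(unclass(want), 1, pmax(rowSums(want), 1), "/")
  m2_plain <- m2
  attr(m2_plain, "empty_rows") <- NULL
  expect_equal(unname(unclass(m2_plain)), unname(want), tolerance = 1e-12)
  populated <- rowSums(m2) > 0
  expect_true(all(abs(rowSums(m2)[populated] - 100) < 1e-6))
})

test_that("epitope segments count maximal consecutive runs per chain", {
  mk_ct <- function(resno, chain = "A") {
    data.frame(ag_chain = chain, ag_resno = resno, stringsAsFactors = FALSE)
  }
  expect_equal(epitope_segments(mk_ct(c(10, 11, 12))), 1L)
  expect_equal(epitope_segments(mk_ct(c(10, 12))), 2L)
  expect_equal(epitope_segments(mk_ct(c(5, 6, 9, 10, 30))), 3L)
  # multiplicity does not matter; chains are summed
  expect_equal(epitope_segments(mk_ct(c(10, 10, 11))), 1L)
  expect_equal(epitope_segments(rbind(mk_ct(c(1, 2)), mk_ct(7, "B"))), 2L)
  # bounds: between 1 and the uER count
  set.seed(3)
  for (i in 1:10) {
    r <- sample(1:40, sample(1:15, 1))
    n <- epitope_segments(mk_ct(r))
    expect_gte(n, 1L)
    expect_lte(n, length(unique(r)))
    if (all(diff(sort(unique(r))) > 1)) expect_equal(n, length(unique(r)))
  }
})

test_that("position-specific frequencies sum to 100 per position", {
  gu <- data.frame(
    structure_id = c("S1", "S2", "S3", "S1"),
    domain = "VH", position = c("107", "107", "107", "31"),
    resno = c(107, 107, 107, 31),
    aa = c("TYR", "TYR", "ARG", "SER"), stringsAsFactors = FALSE)
  pf <- position_aa_frequencies(gu)
  p107 <- pf[pf$position == "107", ]
  expect_equal(p107$pct[p107$aa == "TYR"], 100 * 2 / 3)
  expect_equal(p107$pct[p107$aa == "ARG"], 100 / 3)
  expect_equal(pf$pct[pf$position == "31"], 100)
  sums <- tapply(pf$pct, paste(pf$domain, pf$position), sum)
  expect_true(all(abs(sums - 100) < 1e-9))
})

test_that("Wu-Kabat variability follows N*k/n_mode", {
  expect_equal(wu_kabat(rep("A", 10))$variability, 1)
  expect_equal(wu_kabat(c("A", "C", "D", "E", "F"))$variability, 25)
  wk <- wu_kabat(c("A", "A", "A", "B", "B"))
  expect_equal(wk$variability, 5 * 2 / 3)
  expect_equal(wk$N, 5)
  expect_equal(wk$k, 2)
  expect_equal(wk$n_mode, 3)
  # lower bound 1, attained exactly on conserved columns
  set.seed(9)
  for (i in 1:20) {
    col <- sample(c("A", "C", "G"), sample(1:12, 1), TRUE)
    v <- wu_kabat(col)$variability
    expect_gte(v, 1)
    if (length(unique(col)) == 1) expect_equal(v, 1)
  }
})

test_that("germline mutation fractions use per-position denominators", {
  gu <- data.frame(
    structure_id = rep(sprintf("S%02d", 1:10), each = 1),
    domain = "VH", position = "55", resno = 55,
    aa = c(rep("ARG", 6), rep("GLY", 4)), stringsAsFactors = FALSE)
  germ <- data.frame(structure_id = sprintf("S%02d", 1:10), domain = "VH",
                     position = "55", aa = "G", stringsAsFactors = FALSE)
  gm <- germline_mutation_fraction(gu, germ)
  expect_equal(gm$pct, 60)
  expect_equal(gm$n, 10L)
  expect_equal(attr(gm, "pooled_pct"), 60)

  # identical to germline everywhere: 0%; mutated everywhere: 100%
  germ_same <- transform(germ, aa = "R")
  expect_equal(
    germline_mutation_fraction(gu[1:6, ], germ_same)$pct, 0)
  germ_diff <- transform(germ, aa = "W")
  expect_equal(germline_mutation_fraction(gu, germ_diff)$pct, 100)

  # no overlap: empty result with a warning
  germ_other <- transform(germ, position = "99")
  expect_warning(out <- germline_mutation_fraction(gu, germ_other),
                 "no overlap")
  expect_equal(nrow(out), 0)
})

test_that("frequencies are invariant to contact multiplicity", {
  set.seed(31)
  cx <- mk_random_complex(55, n_ab = 60, n_ag = 60, box = 14)
  ct <- find_contacts(cx, 5)
  expect_gt(nrow(ct), 0)
  doubled <- rbind(ct, ct)
  key <- function(d) abagmap:::.res_key(d$ab_chain, d$ab_resno, d$ab_insert)
  f1 <- aa_frequencies(ct$ab_aa[!duplicated(key(ct))])
  f2 <- aa_frequencies(doubled$ab_aa[!duplicated(key(doubled))])
  expect_equal(f1, f2)
  expect_equal(epitope_segments(ct), epitope_segments(doubled))
  # co-occurrence is contact-weighted by design, but row normalization makes
  # uniform doubling a no-op there too
  expect_equal(cooccurrence_matrix(ct), cooccurrence_matrix(doubled))
})

test_that("epitope secondary-structure shares sum to 100 and honor codes", {
  ct <- data.frame(ag_chain = "A", ag_resno = c(4, 5, 9), ag_insert = "",
                   stringsAsFactors = FALSE)
  ss <- data.frame(chain = "A", resno = c(4, 5), insert = "",
                   code = c("H", "E"), stringsAsFactors = FALSE)
  f <- epitope_ss_frequencies(ct, ss)
  expect_equal(unname(f), c(100 / 3, 100 / 3, 100 / 3))
  # fallback: everything loop
  f0 <- epitope_ss_frequencies(ct, NULL)
  expect_equal(unname(f0["loop"]), 100)
})
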