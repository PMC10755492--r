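# IMGT region assignment, hotspots, CDR capture, secondary structure.

test_that("default region boundaries follow the IMGT definition", {
  sc <- region_scheme()
  expect_equal(as.character(assign_region(27, sc)), "CDR1")
  expect_equal(as.character(assign_region(38, sc)), "CDR1")
  expect_equal(as.character(assign_region(117, sc)), "CDR3")
  expect_equal(as.character(assign_region(105, sc)), "CDR3")
  expect_equal(as.character(assign_region(26, sc)), "FR1")
  expect_equal(as.character(assign_region(39, sc)), "FR2")
  expect_equal(as.character(assign_region(128, sc)), "FR4")
  expect_error(assign_region(129, sc), "outside the variable domain")
  # every VR residue maps to exactly one region; sizes sum to vr_max
  regions <- assign_region(1:128, sc)
  expect_false(anyNA(regions))
  expect_equal(sum(table(regions)), 128)
})

test_that("position 55 moves from FR2 to CDR2 under the expanded scheme", {
  expect_equal(as.character(assign_region(55, region_scheme())), "FR2")
  wide <- region_scheme(cdr2 = c(55, 66))
  expect_equal(as.character(assign_region(55, wide)), "CDR2")
  expect_equal(as.character(assign_region(66, wide)), "CDR2")
  # insertion codes don't affect membership: 111A is CDR3 by numeric part
  expect_equal(as.character(assign_region(111, region_scheme())), "CDR3")
})

test_that("degenerate schemes are rejected", {
  expect_error(region_scheme(cdr1 = c(38, 27)))
  expect_error(region_scheme(cdr2 = c(30, 60)), "disjoint")
  expect_error(region_scheme(cdr3 = c(105, 130)))
})

planted_contacts_at <- function(positions, domain = "VH",
                                aa = rep("TYR", length(positions))) {
  positions <- as.integer(positions)
  n <- length(positions)
  data.frame(
    ab_chain = rep(if (domain == "VH") "H" else "L", n),
    ab_resno = positions, ab_insert = rep("", n), ab_aa = aa,
    ab_atom = rep("CA", n), ab_domain = rep(domain, n),
    ag_chain = rep("A", n), ag_resno = seq_len(n), ag_insert = rep("", n),
    ag_aa = rep("ALA", n), ag_atom = rep("CA", n), distance = rep(4, n),
    stringsAsFactors = FALSE)
}

test_that("uPR region counts and group distributions match hand tallies", {
  # all uPRs in CDR3: that region carries 100%
  ct <- planted_contacts_at(c(106, 108, 110))
  counts <- upr_region_counts(ct)
  expect_equal(counts$n_upr[counts$region == "CDR3"], 3L)
  rd <- region_distribution(list(counts))
  expect_equal(rd$mean_pct$mean_pct[rd$mean_pct$region == "CDR3"], 100)
  expect_equal(sum(rd$mean_pct$mean_pct), 100)

  # planted two-complex group: mean of per-complex proportions, not pooled
  c1 <- upr_region_counts(planted_contacts_at(c(30, 107)))    # 50% CDR1/CDR3
  c2 <- upr_region_counts(planted_contacts_at(c(107, 108, 109, 110)))  # 100% CDR3
  rd2 <- region_distribution(list(c1, c2))
  m <- rd2$mean_pct
  expect_equal(m$mean_pct[m$region == "CDR3"], mean(c(50, 100)))
  expect_equal(m$mean_pct[m$region == "CDR1"], mean(c(50, 0)))
  # per-complex percentages always sum to 100
  sums <- tapply(rd2$per_complex$pct, rd2$per_complex$complex, sum)
  expect_equal(as.numeric(sums), c(100, 100))
})

test_that("paratope proportions use residues actually present", {
  cx <- mk_numbered_antibody(1:128)
  # paratope = exactly the CDR residues
  cdr_ids <- c(27:38, 56:65, 105:117)
  ct <- planted_contacts_at(cdr_ids)
  pp <- paratope_proportions(cx, ct)
  expect_equal(unname(pp["cdr"]), 1.0)
  expect_equal(unname(pp["fr"]), 0.0)
  expect_equal(unname(pp["vr"]), length(cdr_ids) / 128)
  # empty paratope
  pp0 <- paratope_proportions(cx, planted_contacts_at(integer(0)))
  expect_equal(unname(pp0), c(0, 0, 0))
})

test_that("hotspot maps filter by occurrence and use per-position denominators", {
  # 10 complexes; position 107 present in all, uPR in 7; position 55 present
  # in all, uPR in 5; insertion 111A present in only 1 complex (10%: kept
  # inclusively at the default filter? 1/10 = 10% -> retained)
  complexes <- lapply(1:10, function(i) {
    ids <- c(1:110, 111, if (i == 1) 111, 112:128)
    ins <- c(rep("", 111), if (i == 1) "A", rep("", 17))
    mk_numbered_antibody(ids, inserts = ins, structure_id = sprintf("S%03d", i))
  })
  contacts <- lapply(1:10, function(i) {
    pos <- c(if (i <= 7) 107, if (i <= 5) 55)
    planted_contacts_at(pos)
  })
  hs <- hotspot_map(complexes, contacts, min_occurrence = 0.10)
  r107 <- hs[hs$position == "107", ]
  expect_equal(r107$n_present, 10L)
  expect_equal(r107$conditional_pct, 70)
  expect_equal(r107$background_pct, 100)
  r55 <- hs[hs$position == "55", ]
  expect_equal(r55$conditional_pct, 50)
  expect_true("111A" %in% hs$position)  # exactly at the inclusive boundary

  # raising the filter drops sub-threshold positions, never adds rows
  hs2 <- hotspot_map(complexes, contacts, min_occurrence = 0.2)
  expect_false("111A" %in% hs2$position)
  expect_true(nrow(hs2) <= nrow(hs))
  expect_true(all(hs$conditional_pct >= 0 & hs$conditional_pct <= 100))
})

test_that("CDR capture responds to widening the CDR2 boundary", {
  # single uPR at 55: 0% under defaults, 100% under the 55-66 scheme
  ct <- list(planted_contacts_at(55))
  expect_equal(cdr_capture_fraction(ct), 0)
  expect_equal(cdr_capture_fraction(ct, region_scheme(cdr2 = c(55, 66))), 100)

  # 9 planted in-CDR, 1 out: 90%
  grp <- list(planted_contacts_at(c(28:32, 58, 106:108)),  # 9 in CDRs
              planted_contacts_at(45))                     # 1 in FR2
  expect_equal(cdr_capture_fraction(grp), 90)

  # widening any CDR never lowers the captured share
  grp2 <- lapply(c(1, 2), function(i) planted_contacts_at(c(26, 54, 66, 107)))
  narrow <- cdr_capture_fraction(grp2)
  wide <- cdr_capture_fraction(grp2, region_scheme(cdr2 = c(55, 66)))
  wider <- cdr_capture_fraction(grp2, region_scheme(cdr1 = c(26, 38),
                                                    cdr2 = c(54, 66)))
  expect_true(narrow <= wide && wide <= wider)
})

test_that("DSSP codes collapse to exactly three classes", {
  expect_equal(collapse_ss("H"), "helix")
  expect_equal(collapse_ss(c("G", "I")), c("helix", "helix"))
  expect_equal(collapse_ss("E"), "strand")
  expect_equal(collapse_ss("B"), "strand")
  expect_equal(collapse_ss(c("T", "S", " ", "-", "P")), rep("loop", 5))
  expect_equal(collapse_ss(NA), "loop")
  expect_warning(got <- collapse_ss("Z"), "unknown")
  expect_equal(got, "loop")
  # totality over the DSSP alphabet, classes exhaust 100% of any assignment
  codes <- c("H", "G", "I", "E", "B", "T", "S", " ", "P")
  cls <- collapse_ss(codes)
  expect_true(all(cls %in% c("helix", "strand", "loop")))
})

test_that("CDR3 length counts range residues including insertions", {
  expect_equal(cdr3_length(mk_numbered_antibody(1:128), "VH"), 13L)
  cx <- mk_numbered_antibody(c(1:111, 111, 111, 112:128),
                             inserts = c(rep("", 111), "A", "B", rep("", 17)))
  expect_equal(cdr3_length(cx, "VH"), 15L)
  expect_equal(cdr3_length(mk_numbered_antibody(1:50), "VH"), 0L)
})

test_that("DSSP and two-column secondary-structure files parse", {
  dssp <- withr::local_tempfile(fileext = ".dssp")
  writeLines(c(
    "==== Secondary Structure Definition by the program DSSP ====",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
    "    1    4 A M  H  >  ...",
    "    2    5 A K  E     ...",
    "    3        !*            ",
    "    4   10AB G  T     ..."), dssp)
  ss <- read_dssp(dssp)
  expect_equal(ss$resno, c(4, 5, 10))
  expect_equal(ss$chain, c("A", "A", "B"))
  expect_equal(ss$code, c("H", "E", "T"))
  expect_equal(ss$insert, c("", "", "A"))

  tab <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A:4\tH", "A:10A\tE"), tab)
  ss2 <- read_ss_table(tab)
  expect_equal(ss2$resno, c(4, 10))
  expect_equal(ss2$insert, c("", "A"))
  expect_equal(ss2$code, c("H", "E"))
})
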