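# Variable-domain extraction, identity clustering and redundancy removal.

rand_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, TRUE),
        collapse = "")
}

mutate_seq <- function(s, k, seed) {
  set.seed(seed)
  ch <- strsplit(s, "")[[1]]
  pos <- sample(length(ch), k)
  for (p in pos) ch[p] <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                  ch[p])[1]
  paste(ch, collapse = "")
}

test_that("variable-domain sequences stop at IMGT ID 128", {
  cx <- mk_numbered_antibody(1:140, aa = rep("TYR", 140))
  s <- extract_variable_sequence(cx, "VH")
  expect_equal(nchar(s), 128)
  expect_equal(attr(s, "source"), c("TST1", "VH"))

  # insertion residues 111A/111B count (numeric part <= 128)
  cx2 <- mk_numbered_antibody(c(110, 111, 111, 111, 112),
                              inserts = c("", "", "A", "B", ""),
                              aa = c("ALA", "CYS", "ASP", "GLU", "PHE"))
  expect_equal(as.character(extract_variable_sequence(cx2, "VH")), "ACDEF")

  # constant domain only: extraction error
  cx3 <- mk_numbered_antibody(130:210)
  expect_error(extract_variable_sequence(cx3, "VH"), "IMGT ID")
})

test_that("identity is matches over the shorter length, threshold inclusive", {
  base <- rand_seq(100, 1)
  expect_equal(seq_identity(base, base), 1)
  expect_equal(seq_identity(base, mutate_seq(base, 5, 2)), 0.95)
  expect_equal(seq_identity(base, mutate_seq(base, 6, 3)), 0.94)

  # 6 mismatches (0.94): two clusters; 5 mismatches (0.95): one cluster
  two <- cluster_sequences(c(a = base, b = mutate_seq(base, 6, 3)), 0.95)
  expect_equal(length(unique(two)), 2)
  one <- cluster_sequences(c(a = base, b = mutate_seq(base, 5, 2)), 0.95)
  expect_equal(length(unique(one)), 1)
})

test_that("identical sequences always share a cluster", {
  s <- rand_seq(80, 4)
  cl <- cluster_sequences(c(x = s, y = s, z = s), 0.95)
  expect_equal(length(unique(cl)), 1)
})

test_that("clustering at threshold 1.0 merges only identical sequences", {
  base <- rand_seq(100, 5)
  seqs <- c(a = base, b = base, c = mutate_seq(base, 1, 6), d = rand_seq(100, 7))
  cl <- cluster_sequences(seqs, 1.0)
  expect_equal(cl[["a"]], cl[["b"]])
  expect_false(cl[["a"]] == cl[["c"]])
  expect_false(cl[["a"]] == cl[["d"]])
})

test_that("lowering the threshold never increases the cluster count", {
  set.seed(8)
  seqs <- stats::setNames(
    c(vapply(1:6, function(i) mutate_seq(rand_seq(90, 10), i, 20 + i), ""),
      vapply(1:4, function(i) rand_seq(90, 30 + i), "")),
    paste0("s", 1:10))
  counts <- vapply(c(1.0, 0.95, 0.8, 0.5, 0.2),
                   function(th) length(unique(cluster_sequences(seqs, th))),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("Fv antibodies sharing only one chain's cluster are kept", {
  vh <- rand_seq(100, 11)
  vl1 <- rand_seq(100, 12)
  vl2 <- rand_seq(100, 13)
  mk_fv <- function(id, res = 2.0) {
    ab <- rbind(
      do.call(rbind, lapply(1:100, function(i)
        atom_row("H", i, "CA", 3 * i, 0, 0, domain = "VH"))),
      do.call(rbind, lapply(1:100, function(i)
        atom_row("L", i, "CA", 3 * i, 10, 0, domain = "VL"))),
      atom_row("A", 1, "CA", 0, 500, 0, role = "antigen"))
    mk_complex(ab, structure_id = id, resolution = res)
  }
  cx1 <- mk_fv("AAA1"); cx2 <- mk_fv("AAA2")
  vh_cl <- cluster_sequences(c(AAA1 = vh, AAA2 = vh))
  vl_cl <- cluster_sequences(c(AAA1 = vl1, AAA2 = vl2))
  out <- remove_redundant(list(cx1, cx2), vh_cl, vl_cl)
  expect_length(out$complexes, 2)

  # same VH and VL clusters: one representative, best resolution wins
  cx2b <- mk_fv("AAA2", res = 1.8)
  vl_cl2 <- cluster_sequences(c(AAA1 = vl1, AAA2 = vl1))
  out2 <- remove_redundant(list(cx1, cx2b), vh_cl, vl_cl2)
  expect_length(out2$complexes, 1)
  expect_equal(out2$complexes[[1]]$structure_id, "AAA2")
  expect_equal(out2$log$kept, c(FALSE, TRUE))
})

test_that("planted families of sizes 4/3/3 leave exactly 3 survivors", {
  ds <- generate_redundant_dataset(
    3, c(4, 3, 3), mutation_rate = 3, seed = 21,
    base_spec = synthetic_spec(n_ab_residues = 90, antigen_len = 15,
                               domains = "VH",
                               planted_contacts = data.frame(
                                 ab_domain = "VH", ab_pos = 50,
                                 ab_atom = "CB", ag_pos = 8,
                                 ag_atom = "CB", distance = 4.0)))
  expect_length(ds$pdbs, 10)
  complexes <- lapply(names(ds$pdbs), function(id) {
    parse_complex(ds$pdbs[[id]],
                  ds$annotation[ds$annotation$structure_id == id, ])[[1]]
  })
  seqs <- vapply(complexes, function(cx)
    as.character(extract_variable_sequence(cx, "VH")), "")
  names(seqs) <- names(ds$pdbs)
  cl <- cluster_sequences(seqs, 0.95)
  out <- remove_redundant(complexes, vh_clusters = cl)
  ids <- vapply(out$complexes, `[[`, "", "structure_id")
  expect_setequal(ids, ds$truth$survivors)
  # cluster structure matches the planted families
  expect_equal(length(unique(cl)), 3)
  split_fams <- split(names(cl), cl)
  expect_setequal(vapply(split_fams, length, 1L), c(4, 3, 3))
})

test_that("representative selection is order-invariant", {
  ds <- generate_redundant_dataset(
    2, c(3, 2), seed = 31,
    base_spec = synthetic_spec(n_ab_residues = 80, antigen_len = 10,
                               domains = "VH"))
  complexes <- lapply(names(ds$pdbs), function(id) {
    parse_complex(ds$pdbs[[id]],
                  ds$annotation[ds$annotation$structure_id == id, ])[[1]]
  })
  seqs <- vapply(complexes, function(cx)
    as.character(extract_variable_sequence(cx, "VH")), "")
  names(seqs) <- names(ds$pdbs)
  cl <- cluster_sequences(seqs)
  fwd <- remove_redundant(complexes, cl)
  rev_ <- remove_redundant(rev(complexes), cl)
  expect_setequal(vapply(fwd$complexes, `[[`, "", "structure_id"),
                  vapply(rev_$complexes, `[[`, "", "structure_id"))
  expect_setequal(vapply(fwd$complexes, `[[`, "", "structure_id"),
                  ds$truth$survivors)
})

test_that("FASTA export and .clstr reading round-trip cluster members", {
  seqs <- c(AAA1_VH = rand_seq(50, 41), AAA2_VH = rand_seq(50, 42))
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_variable_fasta(seqs, fa)
  lines <- readLines(fa)
  expect_equal(lines[1], ">AAA1_VH")
  expect_equal(lines[2], unname(seqs[1]))

  clstr <- withr::local_tempfile(fileext = ".clstr")
  writeLines(c(">Cluster 0",
               "0\t50aa, >AAA1_VH... *",
               "1\t50aa, >AAA2_VH... at 96%",
               ">Cluster 1",
               "0\t48aa, >BBB1_VH... *"), clstr)
  cl <- read_cdhit_clusters(clstr)
  expect_equal(cl[["AAA1_VH"]], cl[["AAA2_VH"]])
  expect_false(cl[["AAA1_VH"]] == cl[["BBB1_VH"]])
})
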