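test_that("mutation pattern labels parse and round-trip", {
  p <- parse_mutation_pattern("M41L")
  expect_equal(p$position, 41L)
  expect_equal(p$ref, "M")
  expect_equal(p$alts, "L")

  p <- parse_mutation_pattern("T215Y/F")
  expect_equal(p$position, 215L)
  expect_setequal(p$alts, c("Y", "F"))

  # multi-letter alternates with or without "/" are the same pattern
  a <- parse_mutation_pattern("M184VI")
  b <- parse_mutation_pattern("M184V/I")
  expect_equal(a$position, b$position)
  expect_setequal(a$alts, b$alts)

  # parse -> format -> parse is the identity for all ten canonical labels
  for (label in JAGUAR_TEST_LABELS) {
    p1 <- parse_mutation_pattern(label)
    p2 <- parse_mutation_pattern(format_mutation_pattern(p1))
    expect_equal(p1, p2, info = label)
  }
})

test_that("malformed pattern labels are rejected by name", {
  for (bad in c("41L", "M41", "MXL", "M41M", "M0L", "M41L4", "")) {
    expect_error(parse_mutation_pattern(bad), class = "slgeno_parse_error",
                 info = bad)
  }
  expect_error(parse_mutation_pattern("M41B"), "M41B")
})

test_that("call_mutations implements the any-alternate rule", {
  aln <- make_test_alignment(list(
    none = integer(0),          # wild type
    m41 = 1L,                   # M41L only
    m184 = 7L,                  # M184V (first alternate of M184V/I)
    multi = c(1L, 9L)           # M41L + T215Y
  ))
  G <- call_mutations(aln$sequences, aln$patterns, aln$reference)
  expect_equal(dim(G), c(4L, 10L))
  expect_equal(colnames(G), JAGUAR_TEST_LABELS)
  # reference called against itself is all zero
  expect_equal(unname(G["none", ]), rep(0L, 10))
  expect_equal(unname(G["m41", ]), c(1L, rep(0L, 9)))
  expect_equal(G["m184", "M184V/I"], 1L)
  expect_equal(sum(G["m184", ]), 1L)
  expect_equal(unname(G["multi", c("M41L", "T215Y/F")]), c(1L, 1L))

  # second alternate also calls: I at 184
  cells <- strsplit(aln$sequences[["none"]], "")[[1]]
  cells[184] <- "I"
  seqs <- c(alt = paste(cells, collapse = ""))
  G2 <- call_mutations(seqs, aln$patterns, aln$reference)
  expect_equal(G2["alt", "M184V/I"], 1L)
})

test_that("mixtures call when any residue is an alternate; gaps call 0 with warning", {
  aln <- make_test_alignment(list(wt = integer(0)))
  cells <- strsplit(aln$reference, "")[[1]]
  mixed <- as.list(cells)
  mixed[[184]] <- "MV"   # wild type + mutant population mixture
  G <- call_mutations(list(px = unlist(mixed)), aln$patterns, aln$reference)
  expect_equal(G["px", "M184V/I"], 1L)

  gapped <- cells
  gapped[41] <- "X"
  expect_warning(
    G2 <- call_mutations(c(pg = paste(gapped, collapse = "")),
                         aln$patterns, aln$reference),
    "indeterminate")
  expect_equal(G2["pg", "M41L"], 0L)
})

test_that("call_mutations validates alignment and reference residues", {
  aln <- make_test_alignment(list(wt = integer(0)))
  expect_error(
    call_mutations(c(short = substr(aln$sequences[[1]], 1, 100)),
                   aln$patterns, aln$reference),
    class = "slgeno_alignment_error")
  # reference disagreeing with a pattern's wild-type residue
  cells <- strsplit(aln$reference, "")[[1]]
  cells[41] <- "G"
  expect_error(
    call_mutations(aln$sequences, aln$patterns, paste(cells, collapse = "")),
    class = "slgeno_reference_mismatch")
  expect_error(
    call_mutations(aln$sequences, list("A500C"), aln$reference),
    class = "slgeno_alignment_error")
})

test_that("adding an alternate residue is monotone (0 -> 1 only)", {
  sets <- lapply(0:9, function(k) seq_len(k))
  names(sets) <- paste0("pat", 0:9)
  aln <- make_test_alignment(sets)
  base <- call_mutations(aln$sequences, aln$patterns, aln$reference)
  widened <- lapply(aln$patterns, function(p) {
    extra <- setdiff(c("W", "C", "H"), c(p$ref, p$alts))[1]
    parse_mutation_pattern(paste0(p$ref, p$position,
                                  paste(c(p$alts, extra), collapse = "/")))
  })
  wide <- call_mutations(aln$sequences, widened, aln$reference)
  expect_true(all(wide >= base))
})

test_that("FASTA reading and the mutation list file work end to end", {
  skip_if_not_installed("Biostrings")
  aln <- make_test_alignment(list(pat1 = 1L, pat2 = c(1L, 7L)))
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">ref synthetic wild type", aln$reference,
               ">pat1 extra header words", aln$sequences[["pat1"]],
               ">pat2", aln$sequences[["pat2"]]), fa)
  seqs <- read_fasta_aa(fa)
  expect_equal(names(seqs), c("ref", "pat1", "pat2"))
  expect_equal(unname(seqs["ref"]), aln$reference)

  ml <- tempfile(fileext = ".txt")
  writeLines(c("# ddI panel", "M41L", "M184VI   # mixture-style label", ""),
             ml)
  pats <- read_mutation_list(ml)
  expect_length(pats, 2L)
  expect_equal(pats[[2]]$label, "M184V/I")

  G <- call_mutations(seqs[-1], pats, seqs[["ref"]])
  expect_equal(unname(G[, "M41L"]), c(1L, 1L))
  expect_equal(unname(G[, "M184V/I"]), c(0L, 1L))
})

test_that("the bundled synthetic alignment fixtures call cleanly", {
  skip_if_not_installed("Biostrings")
  pats <- read_mutation_list(system.file("extdata", "mutations_ddi.txt",
                                         package = "slgeno"))
  expect_length(pats, 10)
  expect_equal(vapply(pats, format_mutation_pattern, ""),
               JAGUAR_TEST_LABELS)
  ref <- read_fasta_aa(system.file("extdata", "synthetic_rt_reference.fasta",
                                   package = "slgeno"))[[1]]
  aln <- read_fasta_aa(system.file("extdata", "synthetic_rt_alignment.fasta",
                                   package = "slgeno"))
  G <- call_mutations(aln, pats, ref)
  expect_equal(dim(G), c(8L, 10L))
  expect_true(all(G %in% c(0L, 1L)))
  # the synthetic reference itself carries no mutations
  expect_equal(sum(call_mutations(c(ref = ref), pats, ref)), 0L)
})

test_that("dataset CSV round-trips losslessly and rejects bad cells", {
  d <- tiny_dataset(n = 12, p = 3, seed = 7)
  csv <- tempfile(fileext = ".csv")
  write_dataset(d, csv)
  d2 <- read_dataset(csv)
  expect_equal(d2$genotype, d$genotype)
  expect_equal(d2$outcome, d$outcome)

  tab <- utils::read.csv(csv, check.names = FALSE, colClasses = "character")
  bad <- tab; bad[["x2"]][3] <- "2"
  f <- tempfile(fileext = ".csv"); utils::write.csv(bad, f, row.names = FALSE)
  expect_error(read_dataset(f), class = "slgeno_format_error")
  expect_error(read_dataset(f), "row 3")

  bad <- tab; bad[["delta_vl_log10"]][5] <- ""
  f <- tempfile(fileext = ".csv"); utils::write.csv(bad, f, row.names = FALSE)
  expect_error(read_dataset(f), class = "slgeno_format_error")

  bad <- tab; bad$patient_id[2] <- bad$patient_id[1]
  f <- tempfile(fileext = ".csv"); utils::write.csv(bad, f, row.names = FALSE)
  expect_error(read_dataset(f), class = "slgeno_format_error")
})

test_that("prevalence is the column mean and rejects empty input", {
  G <- cbind(a = c(1, 1, 0, 0), b = c(1, 1, 1, 1))
  rownames(G) <- paste0("P", 1:4)
  expect_equal(prevalence(G), c(a = 0.5, b = 1.0))
  expect_error(prevalence(G[0, , drop = FALSE]), class = "slgeno_format_error")
})

test_that("geno_dataset enforces its invariants", {
  G <- matrix(c(0, 1, 1, 0), 2, 2,
              dimnames = list(c("a", "b"), c("m1", "m2")))
  expect_s3_class(geno_dataset(G, c(-1, 0.5)), "geno_dataset")
  expect_error(geno_dataset(G, c(-1, NA)), class = "slgeno_format_error")
  expect_error(geno_dataset(G, -1), class = "slgeno_format_error")
  G2 <- G; G2[1, 1] <- 2
  expect_error(geno_dataset(G2, c(-1, 0.5)), class = "slgeno_format_error")
})
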