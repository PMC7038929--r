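# Chimeric peptide prediction.

test_that("junction sequence assembly joins oriented flanks and truncates at edges", {
  set.seed(21)
  g1 <- rand_dna(1000); g2 <- rand_dna(1000)
  genome <- c(c1 = g1, c2 = g2)
  call <- make_call("A", "B", "c1", 400, "+", "c2", 600, "+")
  js <- build_junction_sequence(call, genome, flank = 200)
  expect_equal(nchar(js$sequence), 400)
  expect_equal(js$junction_offset, 200)
  expect_false(js$truncated)
  expect_equal(js$sequence, paste0(substr(g1, 201, 400), substr(g2, 600, 799)))

  ## truncation near the contig start
  call2 <- make_call("A", "B", "c1", 50, "+", "c2", 600, "+")
  js2 <- build_junction_sequence(call2, genome, flank = 200)
  expect_equal(nchar(js2$sequence), 250)
  expect_equal(js2$junction_offset, 50)
  expect_true(js2$truncated)

  ## minus-strand 5' gene: upstream flank is the reverse complement of the
  ## genomic window starting at the breakpoint
  call3 <- make_call("A", "B", "c1", 400, "-", "c2", 600, "+")
  js3 <- build_junction_sequence(call3, genome, flank = 100)
  expect_equal(substr(js3$sequence, 1, 100), revcomp(substr(g1, 400, 499)))
  ## minus-strand 3' gene mirrors it downstream
  call4 <- make_call("A", "B", "c1", 400, "+", "c2", 600, "-")
  js4 <- build_junction_sequence(call4, genome, flank = 100)
  expect_equal(substr(js4$sequence, 101, 200), revcomp(substr(g2, 501, 600)))

  expect_error(build_junction_sequence(
    make_call("A", "B", "c1", 2000, "+", "c2", 600, "+"), genome), "off contig")
})

test_that("spliced flank mode walks exons instead of genomic windows", {
  set.seed(22)
  chr <- rand_dna(2000)
  genome <- c(c1 = chr)
  ann <- build_annotation(rbind(
    gene_features("A", "c1", "+", iv(c(101, 501), c(200, 600))),
    gene_features("B", "c1", "+", iv(c(1001, 1401), c(1100, 1500)))
  ))
  ## breakpoint at the end of A's exon 1: a 150-bp spliced upstream flank
  ## must stay within the transcript (only 100 bases exist upstream)
  call <- make_call("A", "B", "c1", 200, "+", "c1", 1401, "+")
  js <- build_junction_sequence(call, genome, ann, flank = 150, mode = "spliced")
  expect_equal(js$junction_offset, 100)
  expect_equal(substr(js$sequence, 1, 100), substr(chr, 101, 200))
  ## downstream crosses B's intron: exon2 continues after exon1's 100 bases
  down <- substr(js$sequence, 101, nchar(js$sequence))
  expect_equal(down, paste0(substr(chr, 1401, 1500)))
  ## same call in genomic mode crosses into the intron instead
  jg <- build_junction_sequence(call, genome, ann, flank = 150, mode = "genomic")
  expect_equal(substr(jg$sequence, 1, 150), substr(chr, 51, 200))
})

test_that("three-frame translation tracks stops and the junction residue", {
  js <- list(key = "k", sequence = "ATGGCC", junction_offset = 3)
  fr <- three_frame_translate(js)
  expect_length(fr, 3)
  expect_equal(fr[[1]]$aa, "MA")
  expect_equal(fr[[1]]$junction_residue, 2)   # codon 2 covers base 4
  ## internal stop is emitted as a separator symbol
  js2 <- list(key = "k", sequence = "ATGTAAGGG", junction_offset = 4)
  expect_equal(three_frame_translate(js2)[[1]]$aa, "M*G")
  ## N codons become X; invalid characters error
  js3 <- list(key = "k", sequence = "ATGNNN", junction_offset = 3)
  expect_equal(three_frame_translate(js3)[[1]]$aa, "MX")
  js4 <- list(key = "k", sequence = "ATGQQQ", junction_offset = 3)
  expect_error(three_frame_translate(js4), "non-ACGTN")
})

test_that("tryptic digestion cleaves after K/R except before proline", {
  expect_equal(tryptic_digest("MKRPASK")$fragment, c("MK", "RPASK"))
  expect_equal(tryptic_digest("AAAA")$fragment, "AAAA")
  expect_equal(tryptic_digest("AKRC")$fragment, c("AK", "R", "C"))
  expect_equal(nrow(tryptic_digest("")), 0)
  ## proline rule can be disabled: cleavage after R happens even before P
  expect_equal(tryptic_digest("MKRPASK", proline_rule = FALSE)$fragment,
               c("MK", "R", "PASK"))
  ## missed cleavages add merged fragments
  d1 <- tryptic_digest("AKRC", missed_cleavages = 1)
  expect_true(all(c("AKR", "RC") %in% d1$fragment))
})

test_that("digestion partitions the input for random peptides", {
  set.seed(12)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:300) {
    pep <- paste(sample(aas, sample(1:60, 1), TRUE), collapse = "")
    frags <- tryptic_digest(pep)
    expect_identical(paste(frags$fragment, collapse = ""), pep)
    expect_identical(frags$fragment, oracle_digest(pep))
  }
})

test_that("junction peptides satisfy side minimums and match a planted fixture", {
  ## frame-0 design: ...K / S L I N | A G E R / W W -- the spanning tryptic
  ## fragment is SLIN|AGER with four residues on each side of the junction
  left_aa <- "MMKSLIN"; right_aa <- "AGERWW"
  codon_of <- c(M = "ATG", G = "GGT", S = "AGC", L = "CTG", I = "ATC",
                N = "AAT", K = "AAA", A = "GCT", E = "GAA", R = "CGT",
                W = "TGG")
  enc <- function(aa) paste(codon_of[strsplit(aa, "")[[1]]], collapse = "")
  seq <- paste0(enc(left_aa), enc(right_aa))
  js <- list(key = "fix", sequence = seq,
             junction_offset = nchar(enc(left_aa)))
  peps <- peptides_from_junction(js)
  f0 <- peps[peps$frame == 0, ]
  expect_equal(nrow(f0), 1)
  expect_equal(f0$sequence, "SLINAGER")
  expect_equal(f0$left_len, 4L)
  expect_equal(f0$right_len, 4L)
  oracle <- oracle_junction_peptides(seq, js$junction_offset)
  expect_equal(nrow(merge(peps[, c("frame", "sequence", "left_len", "right_len")],
                          oracle)), nrow(peps))
  expect_equal(nrow(peps), nrow(oracle))
  ## a chimera yields at most one peptide per frame
  expect_true(all(table(peps$frame) <= 1))
  ## no retained peptide contains a stop and all satisfy the side minimum
  expect_false(any(grepl("*", peps$sequence, fixed = TRUE)))
  expect_true(all(peps$left_len >= 2 & peps$right_len >= 2))
})

test_that("junction peptides equal the enumeration oracle on random fixtures", {
  set.seed(77)
  for (i in 1:150) {
    n <- sample(c(60, 90, 120), 1)
    seq <- rand_dna(n)
    off <- sample(10:(n - 10), 1)
    js <- list(key = "r", sequence = seq, junction_offset = off)
    got <- peptides_from_junction(js)
    want <- oracle_junction_peptides(seq, off)
    got <- got[order(got$frame), c("frame", "sequence", "left_len", "right_len")]
    want <- want[order(want$frame), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("stop codon adjacent to the junction suppresses that frame", {
  ## frame 0: L I K | * G E R -> junction residue segment broken by stop
  codon_of <- c(L = "CTG", I = "ATC", K = "AAA", G = "GGT", E = "GAA",
                R = "CGT", A = "GCT", W = "TGG")
  enc <- function(aa) paste(codon_of[strsplit(aa, "")[[1]]], collapse = "")
  seq <- paste0(enc("WWLIK"), "TAA", enc("GER"))
  js <- list(key = "s", sequence = seq, junction_offset = nchar(enc("WWLIK")))
  peps <- peptides_from_junction(js)
  expect_false(0 %in% peps$frame)
  expect_equal(nrow(peps), nrow(oracle_junction_peptides(seq, js$junction_offset)))
})

test_that("peptide database round-trips headers and orders deterministically", {
  peps <- data.frame(key = c("k2", "k1"), frame = c(1L, 0L),
                     sequence = c("LIKAGER", "WWPEPT"),
                     left_len = c(3L, 2L), right_len = c(4L, 4L),
                     stringsAsFactors = FALSE)
  ref <- c(P1 = "MABCDEF", P2 = "MGHIKLM", P0 = "MZZZ")
  fa <- withr::local_tempfile(fileext = ".fa")
  write_peptide_db(peps, ref, fa)
  back <- read_fasta(fa)
  expect_length(back, 5)
  expect_equal(names(back)[3:5], c("P0", "P1", "P2"))  # alphabetical reference
  h <- parse_peptide_header(names(back)[1])
  expect_equal(h$key, "k1"); expect_equal(h$frame, 0L)
  expect_equal(h$left_len, 2L); expect_equal(h$right_len, 4L)
  expect_null(parse_peptide_header("P1"))
  expect_warning(write_peptide_db(peps[0, ], ref, fa), "reference-only")
})

test_that("PSM filtering applies the strict q cutoff and side minimums", {
  db <- data.frame(key = "k", frame = 0L,
                   sequence = c("LIKAGER", "SHORTR"),
                   left_len = c(3L, 1L), right_len = c(4L, 5L),
                   stringsAsFactors = FALSE)
  psms <- data.frame(
    peptide = c("LIKAGER", "LIKAGER", "SHORTR", "UNKNOWN"),
    q_value = c(0.01, 0.05, 0.01, 0.01),
    spectrum_id = paste0("sp", 1:4), sample_id = "m1",
    stringsAsFactors = FALSE
  )
  res <- filter_psms(psms, db)
  expect_equal(res$n_psms, 1)            # q = 0.05 rejected; sides 1/5 rejected
  expect_equal(res$peptides, "LIKAGER")
})

test_that("planted PSM multiplicity is reported as (PSMs, unique peptides)", {
  set.seed(3)
  db <- data.frame(
    key = sprintf("k%02d", 1:20), frame = 0L,
    sequence = vapply(1:20, function(i)
      paste(sample(strsplit("ACDEFGHILMNQSTVWY", "")[[1]], 10, TRUE),
            collapse = ""), character(1)),
    left_len = 3L, right_len = 4L, stringsAsFactors = FALSE
  )
  psms <- simulate_psms(db, sim_config(seed = 5))
  res <- filter_psms(psms, db)
  expect_equal(res$n_psms, 25)
  expect_equal(res$n_peptides, 15)
  ## all q at 0.5 -> nothing accepted
  none <- psms; none$q_value <- 0.5
  expect_equal(filter_psms(none, db)$n_psms, 0)
  ## determinism under the seed
  expect_identical(psms, simulate_psms(db, sim_config(seed = 5)))
})

test_that("side screening labels no-hit, one-side and both-sides peptides", {
  peps <- data.frame(key = c("a", "b", "c"), frame = 0L,
                     sequence = c("QQQWWW", "LIKAGE", "MMMNNN"),
                     left_len = 3L, right_len = 3L, stringsAsFactors = FALSE)
  ref <- c(R1 = "XXLIKXX",        # left half of "LIKAGE" planted
           R2 = "YYMMMNNNYY")     # full third peptide planted contiguously
  res <- side_match_screen(peps, ref)
  expect_equal(res$ref_match, c("no_hit", "one_side", "both_sides"))
})
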