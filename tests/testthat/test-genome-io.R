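test_that("FASTA records are read with correct length and no features", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">rec1 a minimal record", "ATGC"), f)
  recs <- read_genomes(f, "fasta")
  expect_length(recs, 1L)
  expect_equal(recs[[1]]$id, "rec1")
  expect_equal(nchar(recs[[1]]$sequence), 4L)
  expect_equal(nrow(recs[[1]]$features), 0L)
})

test_that("an empty sequence file is an error", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), f)
  expect_error(read_genomes(f, "fasta"), "no sequence records")
  g <- withr::local_tempfile(fileext = ".gbk")
  writeLines("", g)
  expect_error(read_genomes(g, "genbank"), "no sequence records")
})

test_that("GenBank 1-based inclusive coordinates convert to 0-based half-open", {
  f <- withr::local_tempfile(fileext = ".gbk")
  writeLines(c(
    "LOCUS       toy 12 bp    DNA     linear   PHG",
    "FEATURES             Location/Qualifiers",
    "     CDS             complement(1..9)",
    "                     /locus_tag=\"geneA\"",
    "ORIGIN",
    "        1 atgaaataac cc",
    "//"), f)
  rec <- read_genomes(f, "genbank")[[1]]
  expect_equal(rec$sequence, "ATGAAATAACCC")
  expect_equal(rec$features$start, 0L)
  expect_equal(rec$features$end, 9L)
  expect_equal(rec$features$strand, "-")
  expect_equal(rec$features$feature_id, "geneA")
})

test_that("GenBank write/read round-trips features exactly", {
  withr::local_seed(11)
  for (rep in 1:5) {
    n <- sample(200:400, 1)
    nfeat <- sample(1:6, 1)
    start <- sort(sample(0:(n - 30L), nfeat))
    end <- pmin(n, start + sample(9:27, nfeat, replace = TRUE))
    feats <- data.frame(
      feature_id = sprintf("ft%02d", seq_len(nfeat)),
      start = start, end = end,
      strand = sample(c("+", "-"), nfeat, replace = TRUE),
      kind = sample(c("CDS", "other"), nfeat, replace = TRUE),
      stringsAsFactors = FALSE)
    rec <- genome_record("toy", random_dna(n), feats)
    f <- withr::local_tempfile(fileext = ".gbk")
    write_genbank(rec, f)
    back <- read_genomes(f, "genbank")[[1]]
    expect_identical(back$sequence, rec$sequence)
    expect_identical(back$features, rec$features)
  }
})

test_that("GC and AT content follow the unambiguous-base definition", {
  expect_equal(gc_content("ATGC"), 50)
  expect_equal(gc_content("GGCC"), 100)
  expect_equal(gc_content("ATGCNNRY"), 50)  # ambiguity codes excluded
  expect_error(gc_content("NNNN"), "undefined")
  withr::local_seed(5)
  for (i in 1:20) {
    s <- random_dna(sample(10:500, 1))
    expect_equal(gc_content(s) + at_content(s), 100)
  }
})

test_that("DTR detection finds planted borders and degenerate repeats", {
  r <- detect_dtr(paste0("ACGTA", strrep("N", 100), "ACGTA"), min_len = 5)
  expect_equal(r$repeat_length, 5L)
  expect_true(r$found)
  expect_equal(r$unique_length, 105L)
  # homopolymer: maximal allowed border is half the molecule
  expect_equal(detect_dtr(strrep("A", 100))$repeat_length, 50L)
  # no border: found FALSE and unique_length = genome length
  r2 <- detect_dtr(paste0("AAAA", strrep("C", 50), "TTTT"), min_len = 4)
  expect_false(r2$found)
  expect_equal(r2$unique_length, 58L)
  expect_error(detect_dtr("ACGTACGT", min_len = 20), "shorter")
})

test_that("planting a k-mer border on a border-free core yields >= k", {
  withr::local_seed(21)
  for (i in 1:20) {
    k <- sample(5:40, 1)
    border <- random_dna(k)
    core <- random_dna(500)
    r <- detect_dtr(paste0(border, core, border), min_len = 5)
    expect_gte(r$repeat_length, k)
  }
})

test_that("ORF extraction matches the direct translation example", {
  orfs <- extract_orfs("ATGAAATAA", min_aa = 2)
  expect_equal(nrow(orfs), 1L)
  expect_equal(orfs$start, 0L)
  expect_equal(orfs$end, 9L)
  expect_equal(orfs$strand, "+")
  # the reverse complement carries the same ORF on the minus strand
  orfs_rc <- extract_orfs(revcomp("ATGAAATAA"), min_aa = 2)
  expect_equal(nrow(orfs_rc), 1L)
  expect_equal(orfs_rc$strand, "-")
  expect_equal(orfs_rc$start, 0L)
  expect_equal(orfs_rc$end, 9L)
  # stop-free short random sequence has no ORF at all
  expect_equal(nrow(extract_orfs("ATGAAAAAAAAA", min_aa = 30)), 0L)
})

test_that("ORF calls are strand-symmetric over random sequences", {
  withr::local_seed(33)
  for (i in 1:100) {
    s <- random_dna(sample(60:300, 1))
    n <- nchar(s)
    fwd <- extract_orfs(s, min_aa = 5)
    rev <- extract_orfs(revcomp(s), min_aa = 5)
    # map minus-run coordinates back and compare the full sets
    remap <- rev
    if (nrow(remap) > 0L) {
      gs <- n - remap$end
      remap$end <- n - remap$start
      remap$start <- gs
      remap$strand <- ifelse(remap$strand == "+", "-", "+")
      remap$feature_id <- sprintf("orf_%d_%d_%s", remap$start + 1L,
                                  remap$end,
                                  ifelse(remap$strand == "+", "p", "m"))
      remap <- remap[order(remap$start, remap$end, remap$strand), ]
      rownames(remap) <- NULL
    }
    expect_equal(fwd, remap)
  }
})

test_that("genome_stats summarizes length, GC and DTR per record", {
  rec <- genome_record("g", paste0("ACGTAACGT", strrep("GATTACA", 20),
                                   "ACGTAACGT"))
  st <- genome_stats(rec, min_dtr = 5)
  expect_equal(st$dtr_length, 9L)
  expect_true(st$dtr_found)
  expect_equal(st$length_bp, nchar(rec$sequence))
})
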