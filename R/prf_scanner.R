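#' Find slippery-sequence motifs near the 3' end of an ORF
#'
#' Locates exact occurrences of the slippery motif (default the `GTTTTT`
#' hexamer characteristic of tail-assembly-chaperone -1 frameshift sites)
#' whose start lies within the final `window_nt` of the ORF, stop codon
#' included. Minus-strand ORFs are reverse-complemented before the search,
#' so sites are reported 5'->3' on the coding strand.
#'
#' @param record A `GenomeRecord`.
#' @param orf A single feature (one row of the record's feature table, or a
#'   list with `start`, `end`, `strand`, `feature_id`).
#' @param motif Slippery motif to match exactly.
#' @param window_nt Search window measured back from the ORF 3' end; a
#'   window longer than the ORF is truncated to the ORF.
#' @return A list of sites, each with `genome_pos` (0-based coordinate of
#'   the motif start base in genome coordinates), `local_pos` (0-based
#'   position on the coding strand of the ORF), `offset_from_stop` (nt from
#'   motif start to the stop codon start) and `motif`.
#' @export
find_slippery <- function(record, orf, motif = "GTTTTT", window_nt = 60L) {
  orf <- as_feature(orf, nchar(record$sequence))
  cds <- coding_sequence(record, orf)
  orf_len <- nchar(cds)
  window_nt <- min(window_nt, orf_len)
  hits <- gregexpr(paste0("(?=", motif, ")"), cds, perl = TRUE)[[1L]]
  if (hits[1L] == -1L) return(list())
  p <- as.integer(hits) - 1L                    # 0-based local motif starts
  p <- p[p + nchar(motif) <= orf_len]           # motif inside the ORF
  p <- p[p >= orf_len - window_nt]              # within the 3' window
  lapply(p, function(pos) {
    gpos <- if (orf$strand == "+") orf$start + pos else orf$end - 1L - pos
    list(genome_pos = as.integer(gpos),
         local_pos = as.integer(pos),
         offset_from_stop = as.integer((orf_len - 3L) - pos),
         motif = motif)
  })
}

#' Apply a -1 frameshift at a slippery site and measure the extension
#'
#' Translation is modeled as proceeding in frame 0 through the motif, then
#' resuming one nucleotide back (the -1 frame) immediately after the
#' motif's last base. The -1 frame is scanned for stop codons: any stop
#' strictly before the original frame-0 stop codon marks a premature stop;
#' otherwise the extension is the distance in nt from the start of the
#' frame-0 stop codon to the end of the first -1 frame stop at or beyond
#' it. Scanning stops `scan_limit_nt` past the ORF end; if no -1 stop is
#' found by then the result is flagged unterminated.
#'
#' @inheritParams find_slippery
#' @param site A site produced by [find_slippery()] on the same ORF.
#' @param scan_limit_nt Maximum distance scanned past the ORF end.
#' @param threshold_nt Minimum extension for `passes` (the field-reported
#'   "read-through over the locus" is >= 200 nt).
#' @return A `frameshift_result` list: `genome_id`, `orf_id`, `site`,
#'   `extension_nt`, `premature_stop`, `unterminated`, `passes`.
#' @export
minus1_extension <- function(record, orf, site, scan_limit_nt = 3000L,
                             threshold_nt = 200L) {
  if (is.null(site)) stop("minus1_extension: site is absent", call. = FALSE)
  orf <- as_feature(orf, nchar(record$sequence))
  ext_seq <- coding_sequence(record, orf, downstream_nt = scan_limit_nt)
  orf_len <- orf$end - orf$start
  stop0 <- orf_len - 3L                       # frame-0 stop codon start
  slip <- site$local_pos + nchar(site$motif) - 1L  # first -1 frame codon
  at <- seq(slip + 1L, nchar(ext_seq) - 2L, by = 3L)
  cods <- substring(ext_seq, at, at + 2L)
  stops <- (at - 1L)[cods %in% c("TAA", "TAG", "TGA")]  # 0-based starts
  premature <- any(stops < stop0)
  unterminated <- FALSE
  if (premature) {
    extension <- 0L
  } else {
    beyond <- stops[stops >= stop0]
    if (length(beyond) == 0L) {
      unterminated <- TRUE
      extension <- NA_integer_
    } else {
      extension <- as.integer(beyond[1L] + 3L - stop0)
    }
  }
  frameshift_result(
    genome_id = record$id, orf_id = orf$feature_id, site = site,
    extension_nt = extension, premature_stop = premature,
    unterminated = unterminated, threshold_nt = threshold_nt)
}

frameshift_result <- function(genome_id, orf_id, site, extension_nt,
                              premature_stop, unterminated, threshold_nt) {
  passes <- !is.null(site) && !premature_stop && !unterminated &&
    !is.na(extension_nt) && extension_nt >= threshold_nt
  structure(list(genome_id = genome_id, orf_id = orf_id, site = site,
                 extension_nt = extension_nt,
                 premature_stop = premature_stop,
                 unterminated = unterminated, passes = passes),
            class = "frameshift_result")
}

# coding-strand sequence of a feature, optionally with downstream context
# (3' of the ORF in coding orientation), clipped at the genome boundary
coding_sequence <- function(record, orf, downstream_nt = 0L) {
  n <- nchar(record$sequence)
  if (orf$strand == "+") {
    to <- min(n, orf$end + downstream_nt)
    substring(record$sequence, orf$start + 1L, to)
  } else {
    from <- max(0L, orf$start - downstream_nt)
    revcomp(substring(record$sequence, from + 1L, orf$end))
  }
}

as_feature <- function(orf, genome_len) {
  if (is.data.frame(orf)) {
    stopifnot(nrow(orf) == 1L)
    orf <- as.list(orf)
  }
  stopifnot(!is.null(orf$start), !is.null(orf$end), !is.null(orf$strand))
  if (is.null(orf$feature_id)) orf$feature_id <- NA_character_
  orf$start <- as.integer(orf$start); orf$end <- as.integer(orf$end)
  if (orf$start < 0L || orf$start >= orf$end || orf$end > genome_len)
    stop("ORF does not lie within the genome", call. = FALSE)
  orf
}

#' Deduplicate locus alleles
#'
#' Case-insensitive exact deduplication; alleles are returned sorted by
#' descending count, ties broken lexicographically. Counts sum to the
#' number of inputs.
#'
#' @param loci Character vector of locus sequences.
#' @return A data frame with columns `allele` and `count`.
#' @export
dedupe_alleles <- function(loci) {
  if (length(loci) == 0L) stop("dedupe_alleles: empty input", call. = FALSE)
  up <- toupper(loci)
  tab <- table(up)
  out <- data.frame(allele = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$allele), ]
  rownames(out) <- NULL
  out
}

#' Survey a frameshift locus across a genome set
#'
#' Runs [find_slippery()] and [minus1_extension()] on the named ORF of
#' every genome, deduplicates the locus alleles, aligns the unique alleles
#' with [star_msa()] and attaches a [conservation_profile()]. The allele of
#' a genome is its coding-strand sequence from the ORF start through the
#' end of the -1 extension (the ORF alone when the frameshift test fails).
#' When multiple motif sites fall in the window, the one nearest the stop
#' codon is used.
#'
#' @param genomes List of `GenomeRecord`s.
#' @param locus_ids Named character vector mapping genome id to the ORF
#'   `feature_id` (or a two-column data frame `genome_id`, `orf_id`).
#' @param threshold_nt Minimum -1 extension (nt) for a genome to pass.
#' @param motif,window_nt,scan_limit_nt Passed to the scanner.
#' @param scheme Alignment scoring scheme for the allele MSA.
#' @return A `LocusSurvey` list: `n_genomes`, `n_unique_alleles`,
#'   `per_genome` (one row per genome), `alleles`, `msa` and
#'   `conservation` (`NULL` when fewer than two unique alleles exist).
#' @export
survey_locus <- function(genomes, locus_ids, threshold_nt = 200L,
                         motif = "GTTTTT", window_nt = 60L,
                         scan_limit_nt = 3000L, scheme = scoring_scheme()) {
  if (is.data.frame(locus_ids))
    locus_ids <- setNames(locus_ids$orf_id, locus_ids$genome_id)
  rows <- list()
  alleles <- character(length(genomes))
  for (i in seq_along(genomes)) {
    g <- genomes[[i]]
    oid <- if (g$id %in% names(locus_ids)) locus_ids[[g$id]] else NA_character_
    if (is.null(oid) || is.na(oid))
      stop("no locus mapping for genome ", g$id, call. = FALSE)
    hit <- which(g$features$feature_id == oid)
    if (length(hit) != 1L)
      stop("genome ", g$id, " lacks ORF ", oid, call. = FALSE)
    orf <- g$features[hit, ]
    sites <- find_slippery(g, orf, motif = motif, window_nt = window_nt)
    if (length(sites) == 0L) {
      res <- frameshift_result(g$id, oid, site = NULL,
                               extension_nt = NA_integer_,
                               premature_stop = FALSE, unterminated = FALSE,
                               threshold_nt = threshold_nt)
    } else {
      site <- sites[[which.min(vapply(sites, `[[`, integer(1L),
                                      "offset_from_stop"))]]
      res <- minus1_extension(g, orf, site, scan_limit_nt = scan_limit_nt,
                              threshold_nt = threshold_nt)
    }
    # extension is measured from the frame-0 stop codon START, so the
    # region past the ORF end (stop codon included) is extension - 3 nt
    ext <- if (!is.null(res$site) && res$passes)
      max(0L, res$extension_nt - 3L) else 0L
    alleles[i] <- coding_sequence(g, as_feature(orf, nchar(g$sequence)),
                                  downstream_nt = ext)
    rows[[i]] <- data.frame(
      genome_id = g$id, orf_id = oid,
      site_found = !is.null(res$site),
      genome_pos = if (!is.null(res$site)) res$site$genome_pos else NA_integer_,
      offset_from_stop = if (!is.null(res$site)) res$site$offset_from_stop
                         else NA_integer_,
      extension_nt = res$extension_nt,
      premature_stop = res$premature_stop,
      unterminated = res$unterminated,
      passes = res$passes, stringsAsFactors = FALSE)
  }
  per_genome <- do.call(rbind, rows)
  allele_tab <- dedupe_alleles(alleles)
  msa <- NULL
  cons <- NULL
  if (nrow(allele_tab) >= 2L) {
    msa <- star_msa(allele_tab$allele, scheme = scheme,
                    ids = sprintf("allele%d", seq_len(nrow(allele_tab))))
    cons <- conservation_profile(msa)
  }
  structure(list(n_genomes = length(genomes),
                 n_unique_alleles = nrow(allele_tab),
                 per_genome = per_genome, alleles = allele_tab,
                 msa = msa, conservation = cons),
            class = "LocusSurvey")
}

#' @export
print.LocusSurvey <- function(x, ...) {
  cat(sprintf(
    "LocusSurvey: %d genome(s), %d unique allele(s), %d/%d pass\n",
    x$n_genomes, x$n_unique_alleles, sum(x$per_genome$passes), x$n_genomes))
  invisible(x)
}
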