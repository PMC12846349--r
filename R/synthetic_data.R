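#' Parameters of the infection-dynamics simulator
#'
#' A compartment model (susceptible, infected-by-age, resistant, free
#' phage) used to emulate killing-curve and one-step-growth data with
#' known ground truth. The simulators stand in for unpublished raw assay
#' data; their parameters are chosen per experiment and carry no claim
#' about any particular phage.
#'
#' @param r Bacterial growth rate, per minute.
#' @param K Carrying capacity in OD units.
#' @param k_ads Adsorption rate constant, mL cell^-1 min^-1.
#' @param latent_min Latent period in minutes (infection to lysis).
#' @param burst Virions released per lysed cell (>= 1).
#' @param resistant_frac Fraction of the inoculum resistant to infection.
#' @param noise_sd Multiplicative lognormal noise sigma per reading.
#' @param seed Integer seed; every generator is a pure function of it.
#' @return An `infection_params` list.
#' @export
infection_params <- function(r = 0.025, K = 1.0, k_ads = 3e-11,
                             latent_min = 20, burst = 60,
                             resistant_frac = 1e-6, noise_sd = 0.05,
                             seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  stopifnot(r >= 0, K > 0, k_ads >= 0, latent_min >= 0, burst >= 1,
            resistant_frac >= 0, resistant_frac < 1, noise_sd >= 0)
  structure(list(r = r, K = K, k_ads = k_ads, latent_min = latent_min,
                 burst = burst, resistant_frac = resistant_frac,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "infection_params")
}

#' Simulate phage killing curves over an MOI ladder
#'
#' Forward-Euler integration (step <= 0.5 min, with internal step-halving
#' whenever a state would go negative) of susceptible (B), infected (I,
#' age-structured so cells lyse `latent_min` after infection, releasing
#' `burst` phage each), resistant (R) and free-phage (P) compartments:
#' `dB/dt = r B (1 - (B+I+R)/K) - k_ads B P`, with R growing logistically
#' and unexposed. The OD proxy is `B + I + R` (1 OD = 1e9 cells/mL);
#' multiplicative lognormal noise is applied per reading. Deterministic
#' per seed.
#'
#' @param params An [infection_params()].
#' @param mois Numeric vector of MOIs (may be empty for a control-only
#'   set).
#' @param times Sampling times in minutes.
#' @param od0 Inoculum OD at time zero.
#' @return A [growth_curve_set()] with one curve per MOI plus the
#'   phage-free control.
#' @export
simulate_growth_curves <- function(params, mois = numeric(0),
                                   times = seq(0, 390, by = 30),
                                   od0 = 0.05) {
  stopifnot(inherits(params, "infection_params"))
  withr::with_seed(params$seed, {
    cells_per_od <- 1e9
    run <- function(moi) {
      p0 <- moi * od0 * cells_per_od
      od <- integrate_infection(params, times, od0, p0, cells_per_od)
      if (params$noise_sd > 0)
        od <- od * exp(rnorm(length(od), 0, params$noise_sd))
      od
    }
    control <- run(0)
    curves <- setNames(lapply(mois, run), as.character(mois))
    growth_curve_set(times, control, curves,
                     window_end = detect_window_end(times, control))
  })
}

integrate_infection <- function(params, times, od0, p0, cells_per_od) {
  dt <- 0.5                                # minutes; fine enough for r ~ 1/h
  n_steps <- as.integer(ceiling(max(times) / dt))
  latent_steps <- max(1L, as.integer(round(params$latent_min / dt)))
  B <- od0 * (1 - params$resistant_frac)
  R <- od0 * params$resistant_frac
  P <- p0
  q <- numeric(n_steps)                    # biomass newly infected per step
  od <- numeric(n_steps + 1L)
  od[1L] <- B + R
  for (s in seq_len(n_steps)) {
    if (s > latent_steps) {                # cohort completes its latent period
      P <- P + params$burst * q[s - latent_steps] * cells_per_od
    }
    incubating <- if (s > 1L)
      sum(q[max(1L, s - latent_steps):(s - 1L)]) else 0
    crowd <- 1 - (B + incubating + R) / params$K
    growth <- params$r * B * crowd * dt
    # fluxes are capped at the available amount so no state goes negative
    newly_inf <- min(params$k_ads * P * B * dt, max(0, B + growth))
    B <- max(0, B + growth - newly_inf)
    R <- max(0, R + params$r * R * crowd * dt)
    ads <- min(params$k_ads * P * (B + incubating + R) * cells_per_od * dt, P)
    P <- P - ads
    q[s] <- newly_inf
    od[s + 1L] <- B + sum(q[max(1L, s - latent_steps + 1L):s]) + R
  }
  stats::approx(seq(0, by = dt, length.out = n_steps + 1L), od,
                xout = times, rule = 2)$y
}

#' Simulate a one-step growth titer curve
#'
#' Piecewise titer trajectory: baseline `n0` until the latent period, a
#' linear rise over `rise_min` to `n0 * burst`, a plateau, and optionally
#' a second (slower, larger) rise and plateau emulating a second round of
#' infection. Multiplicative lognormal noise per reading; ground truth is
#' attached as the `"truth"` attribute for parameter-recovery tests.
#'
#' @param params An [infection_params()] (uses `latent_min`, `burst`,
#'   `noise_sd`, `seed`).
#' @param times Sampling times in minutes.
#' @param n0 Phage input at t0 (PFU; volume is taken as 1 mL).
#' @param rise_min Duration of the first rise, minutes.
#' @param plateau_min Duration of the first plateau before any second
#'   rise, minutes.
#' @param second_burst Add a second rise and plateau?
#' @param second_rise_min Duration of the second rise, minutes.
#' @param second_factor Fold increase of the second plateau over the
#'   first.
#' @return A [titer_series()] with attribute `truth` (a list with
#'   `latent_min`, `burst`, `n0`).
#' @export
simulate_one_step <- function(params, times = seq(0, 70, by = 10),
                              n0 = 1e4, rise_min = 10, plateau_min = 10,
                              second_burst = TRUE, second_rise_min = 20,
                              second_factor = 40) {
  stopifnot(inherits(params, "infection_params"))
  L <- params$latent_min; beta <- params$burst
  p1 <- n0 * beta
  t1 <- L + rise_min                 # first plateau start
  t2 <- t1 + plateau_min             # second rise start
  t3 <- t2 + second_rise_min         # second plateau start
  titer <- vapply(times, function(t) {
    if (beta <= 1 + 1e-9) return(n0)     # degenerate: no burst at all
    if (t <= L) n0
    else if (t < t1) n0 + (p1 - n0) * (t - L) / rise_min
    else if (!second_burst || t < t2) p1
    else if (t < t3) p1 + (p1 * (second_factor - 1)) * (t - t2) / second_rise_min
    else p1 * second_factor
  }, numeric(1L))
  withr::with_seed(params$seed, {
    if (params$noise_sd > 0)
      titer <- titer * exp(rnorm(length(titer), 0, params$noise_sd))
  })
  out <- titer_series(times, titer, n0 = n0, volume_ml = 1)
  attr(out, "truth") <- list(latent_min = L, burst = beta, n0 = n0)
  out
}

#' Simulate an exponential adsorption decay curve
#'
#' Free phage decays as `P(t) = p0 * exp(-k * cells * t)` with
#' multiplicative lognormal noise. Ground truth `k` is attached as the
#' `"truth"` attribute.
#'
#' @param p0 Initial free-phage titer (PFU/mL).
#' @param k Adsorption rate constant, mL cell^-1 min^-1.
#' @param cells Host cell density, cells/mL.
#' @param times Sampling times in minutes.
#' @param noise_sd Lognormal sigma per reading.
#' @param seed Integer seed.
#' @return A [titer_series()] with attribute `truth` (list with `k`,
#'   `cells`, `p0`).
#' @export
simulate_adsorption <- function(p0 = 1e6, k = 3e-10, cells = 2e8,
                                times = c(0, 1, 2, 3, 4, 5, 10, 15),
                                noise_sd = 0, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  titer <- p0 * exp(-k * cells * times)
  withr::with_seed(as.integer(seed), {
    if (noise_sd > 0)
      titer <- titer * exp(rnorm(length(titer), 0, noise_sd))
  })
  out <- titer_series(times, titer, n0 = p0, volume_ml = 1)
  attr(out, "truth") <- list(k = k, cells = cells, p0 = p0)
  out
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Generate synthetic genomes carrying a -1 PRF tail-chaperone locus
#'
#' Each genome embeds a tail-assembly-chaperone-like ORF whose 3' end
#' carries the slippery motif followed by the frame-0 stop, and whose -1
#' reading frame runs stop-free past the ORF for (at least)
#' `extension_len` nt before a planted -1 stop. Divergence is applied
#' per site but only where it preserves the motif, the frame-0 ORF
#' structure and the -1 stop structure, so positives remain positives.
#' Negatives either scramble the motif (site absent) or plant a -1 stop
#' ~30 nt before the frame-0 stop (premature stop). Optionally a direct
#' terminal repeat of `dtr_len` nt is planted at both ends.
#'
#' @param n_genomes Number of genomes.
#' @param locus_len ORF length in nt (rounded up to a codon multiple).
#' @param motif Slippery motif (default `GTTTTT`).
#' @param extension_len Requested -1 extension in nt; the realized value
#'   (reported in the truth table) is the smallest frame-compatible
#'   length at or above it.
#' @param divergence Per-site substitution probability applied to the
#'   locus of each genome.
#' @param negatives Character vector of length `n_genomes` with values
#'   `"none"`, `"scramble_motif"` or `"plant_minus1_stop"`; default all
#'   positive.
#' @param dtr_len Planted direct-terminal-repeat length (0 for none).
#' @param seed Integer seed.
#' @param background_len Length of random sequence flanking the locus.
#' @param strand Per-genome strand of the locus (`"+"`/`"-"`; recycled).
#' @return A list with `genomes` (list of [genome_record()]s, each with a
#'   single CDS feature `tac_orf`) and `truth` (data frame with
#'   `genome_id`, `negative`, `expected_pass`, `expected_site`,
#'   `expected_premature`, `extension_nt`, `strand`, `dtr_len`).
#' @export
make_prf_genomes <- function(n_genomes, locus_len = 300L,
                             motif = "GTTTTT", extension_len = 300L,
                             divergence = 0.05,
                             negatives = rep("none", n_genomes),
                             dtr_len = 0L, seed,
                             background_len = 1000L, strand = "+") {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  stopifnot(n_genomes >= 1L, extension_len > 0L)
  if (divergence < 0 || divergence >= 0.75)
    stop("divergence must lie in [0, 0.75)", call. = FALSE)
  if (length(negatives) != n_genomes ||
      !all(negatives %in% c("none", "scramble_motif", "plant_minus1_stop")))
    stop("negatives must give 'none', 'scramble_motif' or ",
         "'plant_minus1_stop' for each genome", call. = FALSE)
  strand <- rep(strand, length.out = n_genomes)

  layout <- locus_layout(locus_len, motif, extension_len)
  withr::with_seed(as.integer(seed), {
    root <- build_root_locus(layout, motif)
    genomes <- vector("list", n_genomes)
    truth <- vector("list", n_genomes)
    for (i in seq_len(n_genomes)) {
      loc <- diverge_locus(root, layout, motif, divergence)
      neg <- negatives[i]
      if (neg == "scramble_motif") loc <- scramble_motif(loc, layout, motif)
      if (neg == "plant_minus1_stop")
        loc <- plant_premature_stop(loc, layout)
      gid <- sprintf("g%03d", i)
      genomes[[i]] <- assemble_genome(gid, loc, layout, dtr_len,
                                      background_len, strand[i])
      truth[[i]] <- data.frame(
        genome_id = gid, negative = neg,
        expected_pass = neg == "none",
        expected_site = neg != "scramble_motif",
        expected_premature = neg == "plant_minus1_stop",
        extension_nt = if (neg == "none") layout$ext_realized else NA_integer_,
        strand = strand[i], dtr_len = as.integer(dtr_len),
        stringsAsFactors = FALSE)
    }
    list(genomes = genomes, truth = do.call(rbind, truth))
  })
}

# fixed geometry of the synthetic locus, all 0-based local coordinates on
# the coding strand: ORF [0, orf_len), motif at p, slip site at p+5,
# frame-0 stop at stop0, planted -1 stop at sstar
locus_layout <- function(locus_len, motif, extension_len) {
  orf_len <- as.integer(3L * ceiling(max(locus_len, 90L) / 3L))
  stop0 <- orf_len - 3L
  p <- stop0 - 45L                       # motif start; inside 60 nt window
  slip <- p + nchar(motif) - 1L          # first -1 frame codon start
  smin <- stop0 + extension_len - 3L
  sstar <- smin + (3L - ((smin - slip) %% 3L)) %% 3L
  list(orf_len = orf_len, stop0 = stop0, p = p, slip = slip,
       sstar = sstar, total = sstar + 3L,
       ext_realized = sstar + 3L - stop0,
       fixed = c(1:3, (p + 1L):(p + nchar(motif)),
                 (stop0 + 1L):(stop0 + 3L), (sstar + 1L):(sstar + 3L)))
}

# random locus satisfying all frame constraints, by iterative repair
build_root_locus <- function(layout, motif) {
  x <- sample(c("A", "C", "G", "T"), layout$total, replace = TRUE)
  x[1:3] <- c("A", "T", "G")
  x[(layout$p + 1L):(layout$p + nchar(motif))] <- strsplit(motif, "")[[1L]]
  x[(layout$stop0 + 1L):(layout$stop0 + 3L)] <- c("T", "A", "A")
  x[(layout$sstar + 1L):(layout$sstar + 3L)] <- c("T", "A", "A")
  for (iter in 1:500) {
    bad <- locus_violations(x, layout, motif)
    if (length(bad) == 0L) return(x)
    pos <- bad[!(bad %in% layout$fixed)]
    if (length(pos) == 0L)
      stop("locus constraints unsatisfiable with this geometry",
           call. = FALSE)
    j <- pos[1L]
    x[j] <- sample(setdiff(c("A", "C", "G", "T"), x[j]), 1L)
  }
  stop("failed to build a constraint-satisfying locus", call. = FALSE)
}

# returns 1-based positions involved in any constraint violation
locus_violations <- function(x, layout, motif) {
  s <- paste(x, collapse = "")
  bad <- integer(0)
  # frame-0: no stop strictly inside the ORF
  at0 <- seq(4L, layout$stop0 - 2L, by = 3L)
  stops0 <- at0[substring(s, at0, at0 + 2L) %in% STOP_CODONS]
  for (a in stops0) bad <- c(bad, a:(a + 2L))
  # -1 frame: stop-free from the slip site up to the planted stop
  at1 <- seq(layout$slip + 1L, layout$sstar - 2L, by = 3L)
  stops1 <- at1[substring(s, at1, at1 + 2L) %in% STOP_CODONS]
  for (a in stops1) bad <- c(bad, a:(a + 2L))
  # exactly one motif occurrence inside the 3' search window of the ORF
  w0 <- max(0L, layout$orf_len - 60L)
  occ <- gregexpr(paste0("(?=", motif, ")"), s, perl = TRUE)[[1L]]
  occ <- if (occ[1L] == -1L) integer(0) else as.integer(occ) - 1L
  occ <- occ[occ >= w0 & occ + nchar(motif) <= layout$orf_len]
  spurious <- setdiff(occ, layout$p)
  for (a in spurious) bad <- c(bad, (a + 1L):(a + nchar(motif)))
  unique(bad)
}

# per-site substitutions that leave every constraint intact
diverge_locus <- function(root, layout, motif, divergence) {
  if (divergence == 0) return(root)
  x <- root
  mutable <- setdiff(seq_along(x), layout$fixed)
  hit <- mutable[runif(length(mutable)) < divergence]
  for (j in hit) {
    old <- x[j]
    x[j] <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
    if (length(locus_violations(x, layout, motif)) > 0L) x[j] <- old
  }
  x
}

scramble_motif <- function(x, layout, motif) {
  mpos <- (layout$p + 1L):(layout$p + nchar(motif))
  for (iter in 1:100) {
    cand <- x
    cand[mpos] <- sample(c("A", "C", "G"), nchar(motif), replace = TRUE)
    # keep the ORF intact apart from the motif loss; a scrambled motif
    # must not recreate the motif nor introduce frame-0 stops
    s <- paste(cand, collapse = "")
    at0 <- seq(4L, layout$stop0 - 2L, by = 3L)
    has_stop0 <- any(substring(s, at0, at0 + 2L) %in% STOP_CODONS)
    w0 <- max(0L, layout$orf_len - 60L)
    occ <- gregexpr(paste0("(?=", motif, ")"), s, perl = TRUE)[[1L]]
    occ <- if (occ[1L] == -1L) integer(0) else as.integer(occ) - 1L
    occ <- occ[occ >= w0 & occ + nchar(motif) <= layout$orf_len]
    if (!has_stop0 && length(occ) == 0L) return(cand)
  }
  stop("failed to scramble motif", call. = FALSE)
}

plant_premature_stop <- function(x, layout) {
  # candidate -1 frame codon starts (0-based), from ~30 nt before the
  # frame-0 stop backwards, staying at or after the slip site
  cand <- seq(layout$slip, layout$stop0 - 3L, by = 3L)
  cand <- rev(cand[cand <= layout$stop0 - 30L + 3L])
  if (length(cand) == 0L) cand <- rev(seq(layout$slip, layout$stop0 - 3L, 3L))
  for (q in cand) {
    y <- x
    y[(q + 1L):(q + 3L)] <- c("T", "A", "A")
    s <- paste(y, collapse = "")
    # the ORF must stay valid in frame 0 and the motif intact
    at0 <- seq(4L, layout$stop0 - 2L, by = 3L)
    ok0 <- !any(substring(s, at0, at0 + 2L) %in% STOP_CODONS)
    motif_ok <- substring(s, layout$p + 1L, layout$p + 6L) ==
      substring(paste(x, collapse = ""), layout$p + 1L, layout$p + 6L)
    if (ok0 && motif_ok) return(y)
  }
  stop("could not plant a -1 frame stop", call. = FALSE)
}

assemble_genome <- function(gid, loc, layout, dtr_len, background_len,
                            strand) {
  bases <- c("A", "C", "G", "T")
  for (iter in 1:50) {
    left <- sample(bases, background_len, replace = TRUE)
    right <- sample(bases, max(50L, background_len %/% 2L), replace = TRUE)
    core <- c(left, loc, right)
    if (dtr_len > 0L) {
      rep_seq <- sample(bases, dtr_len, replace = TRUE)
      g <- c(rep_seq, core, rep_seq)
      s <- paste(g, collapse = "")
      # reject the rare draw whose border extends past the planted repeat
      if (kmp_border_cpp(s, nchar(s) %/% 2L) != dtr_len) next
      orf_start <- dtr_len + length(left)
    } else {
      g <- core
      s <- paste(g, collapse = "")
      orf_start <- length(left)
    }
    orf_end <- orf_start + layout$orf_len
    n <- nchar(s)
    if (strand == "-") {
      s <- revcomp(s)
      feat <- data.frame(feature_id = "tac_orf", start = n - orf_end,
                         end = n - orf_start, strand = "-", kind = "CDS",
                         stringsAsFactors = FALSE)
    } else {
      feat <- data.frame(feature_id = "tac_orf", start = orf_start,
                         end = orf_end, strand = "+", kind = "CDS",
                         stringsAsFactors = FALSE)
    }
    return(genome_record(gid, s, feat, source = "synthetic"))
  }
  stop("failed to assemble genome without a spurious terminal repeat",
       call. = FALSE)
}

#' Generate a synthetic strain-by-defense-system presence/absence table
#'
#' Group labels are Bernoulli(`group_frac`); presence of each system is
#' Bernoulli with baseline `prevalence`, with the log-odds shifted by
#' `log(OR)` in the focal group for systems named in `enriched`.
#'
#' @param n_strains,n_systems Table dimensions (`n_systems >= 1`).
#' @param prevalence Baseline presence probability.
#' @param enriched Named numeric vector mapping system name to its odds
#'   ratio in the focal group (systems default to OR = 1).
#' @param group_frac Probability a strain belongs to the focal group.
#' @param seed Integer seed.
#' @param group_labels Labels for the focal and other group.
#' @return A [presence_absence_table()]; attribute `truth` holds the
#'   per-system odds ratios.
#' @export
make_defense_table <- function(n_strains, n_systems, prevalence = 0.3,
                               enriched = numeric(0), group_frac = 0.5,
                               seed, group_labels = c("focal", "other")) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (n_systems < 1L) stop("n_systems must be >= 1", call. = FALSE)
  systems <- sprintf("sys%02d", seq_len(n_systems))
  ors <- setNames(rep(1, n_systems), systems)
  if (length(enriched) > 0L) {
    if (is.null(names(enriched)) ||
        !all(names(enriched) %in% systems))
      stop("enriched must be named by system", call. = FALSE)
    ors[names(enriched)] <- enriched
  }
  withr::with_seed(as.integer(seed), {
    grp <- ifelse(runif(n_strains) < group_frac,
                  group_labels[1L], group_labels[2L])
    base_logit <- stats::qlogis(prevalence)
    mat <- vapply(systems, function(sys) {
      pp <- stats::plogis(base_logit +
                            ifelse(grp == group_labels[1L],
                                   log(ors[[sys]]), 0))
      runif(n_strains) < pp
    }, logical(n_strains))
    colnames(mat) <- systems
    out <- presence_absence_table(sprintf("strain%03d", seq_len(n_strains)),
                                  grp, mat)
    attr(out, "truth") <- ors
    out
  })
}
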