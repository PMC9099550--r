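#' Synthetic study configuration
#'
#' Default parameters of the synthetic generators, chosen to match the
#' regimes of routine clinical transport: carrier walks of about 5.5 min
#' with a stable ~4 Hz gait line and sub-2.4 g amplitudes; pneumatic-tube
#' journeys of about 2.4 min dominated by heavy-tailed shocks (on the order
#' of 116 excursions above 2.5 g) on a modest noise floor, recorded at
#' 25 Hz with per-axis saturation at +/-16 g; unimodal right-skewed particle
#' size distributions peaking near 100 nm in the 10-1000 nm window; and
#' log-normal peptide intensities with intensity-dependent (MNAR)
#' missingness, donor effects, technical triplicates and two injections.
#'
#' @param ... Named overrides of any top-level entry (list entries are
#'   replaced wholesale).
#' @return Nested list of class `synth_config`.
#' @export
synth_config <- function(...) {
  cfg <- list(
    sample_rate = 25,          # Hz
    clip_limit = 16,           # g per axis
    carrier = list(
      duration_min = 5.5,
      ground_freq = 4.0,       # Hz gait fundamental
      amp_fund = 0.30,         # g, vertical fundamental
      amp_harm = 0.10,         # g, 2nd harmonic
      amp_lateral = 0.08,      # g, horizontal components
      phase_jitter = 0.02,     # rad per sample random-walk
      noise_sd = 0.05          # g per axis
    ),
    pts = list(
      duration_min = 2.4,
      n_shocks = 116,          # expected count of >2.5 g excursions
      shock_alpha = 1.5,       # Pareto tail index of shock amplitude
      shock_min = 3,           # g
      shock_max = 25,          # g (vector amplitude before per-axis clip)
      rise = 0.02,             # s
      decay = 0.08,            # s
      noise_sd = 0.15          # g per axis
    ),
    particles = list(
      bins = seq(15, 995, by = 10),  # nm grid
      mode = 100,              # nm
      gsd = 1.6,               # geometric SD
      total = 5e9,             # particles/mL (diluted)
      noise_sd = 0.08,         # multiplicative log-noise per bin
      dilution = 1000
    ),
    proteome = list(
      n_donors = 12,
      n_proteins = 300,
      peptides_per_protein = 5,
      base_mean = 23, base_sd = 2,       # log2 protein level
      pep_sd = 1,                        # log2 peptide offset spread
      donor_sd = 0.3,
      rep_sd = 0.25,
      inj_sd = 0.1,
      miss_mid = 19.5,                   # log2 intensity of 50% missingness
      miss_scale = 0.8,
      n_diff = 10, diff_effect = 3,      # planted PTS shift, log2
      n_corr = 10, corr_slope = 0.8,     # planted metric-linked proteins
      corr_noise = 0.3
    ),
    blood = list(
      ranges = list(Ec = c(4.2e6, 6.1e6), Lc = c(4e3, 10e3),
                    Ly = c(1e3, 4e3), Mc = c(200, 800),
                    Gc = c(2e3, 7e3), Tc = c(1.5e5, 4e5),
                    HGB = c(120, 170)),
      ec_hgb_rho = 0.9
    )
  )
  ov <- list(...)
  for (nm in names(ov)) cfg[[nm]] <- ov[[nm]]
  structure(cfg, class = "synth_config")
}

.seed_int <- function(seed) as.integer(abs(seed) %% (.Machine$integer.max - 1))

#' Generate a synthetic transport acceleration trace
#'
#' Carrier (`"C"`) traces are gravity plus a fundamental-and-harmonic gait
#' oscillation, mostly vertical (so the oscillation rides on the 1 g
#' baseline and its sign survives in the acceleration magnitude), with
#' phase-jittered harmonics, weaker lateral components, and Gaussian sensor
#' noise. Pneumatic-tube (`"PTS"`) traces are gravity plus baseline noise
#' and Poisson-timed biexponential shock pulses with truncated-Pareto
#' amplitudes and uniformly random 3D orientation, clipped per axis at the
#' sensor limit so near-saturation maxima occur.
#'
#' @param mode `"C"` or `"PTS"`.
#' @param config A [synth_config()].
#' @param seed Integer seed.
#' @return An [accel_trace()].
#' @export
gen_accel_trace <- function(mode = c("C", "PTS"), config = synth_config(),
                            seed = 1) {
  mode <- match.arg(mode)
  set.seed(.seed_int(seed))
  sr <- config$sample_rate
  dt <- 1 / sr
  p <- if (mode == "C") config$carrier else config$pts
  t <- seq(0, p$duration_min * 60, by = dt)
  n <- length(t)
  if (mode == "C") {
    phase <- cumsum(stats::rnorm(n, 0, p$phase_jitter))
    az <- 1 + p$amp_fund * sin(2 * pi * p$ground_freq * t + phase) +
      p$amp_harm * sin(2 * pi * 2 * p$ground_freq * t + 2 * phase) +
      stats::rnorm(n, 0, p$noise_sd)
    ax <- p$amp_lateral * sin(2 * pi * p$ground_freq * t + phase + pi / 3) +
      stats::rnorm(n, 0, p$noise_sd)
    ay <- p$amp_lateral * sin(2 * pi * p$ground_freq * t + phase + 2 * pi / 3) +
      stats::rnorm(n, 0, p$noise_sd)
  } else {
    ax <- stats::rnorm(n, 0, p$noise_sd)
    ay <- stats::rnorm(n, 0, p$noise_sd)
    az <- 1 + stats::rnorm(n, 0, p$noise_sd)
    k <- stats::rpois(1, p$n_shocks)
    if (k > 0) {
      # biexponential pulse sampled on the grid, normalized to unit peak
      off <- seq(0, 0.6, by = dt)
      pulse <- exp(-off / p$decay) - exp(-off / p$rise)
      pulse <- pulse / max(pulse)
      u <- stats::runif(k)
      amin <- p$shock_min; amax <- p$shock_max; al <- p$shock_alpha
      # truncated Pareto inverse CDF
      amp <- amin / (1 - u * (1 - (amin / amax)^al))^(1 / al)
      at <- sample.int(n, k, replace = TRUE)
      for (s in seq_len(k)) {
        dir <- stats::rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        idx <- at[s]:min(n, at[s] + length(pulse) - 1L)
        seg <- pulse[seq_along(idx)] * amp[s]
        ax[idx] <- ax[idx] + dir[1] * seg
        ay[idx] <- ay[idx] + dir[2] * seg
        az[idx] <- az[idx] + dir[3] * seg
      }
    }
  }
  cl <- config$clip_limit
  accel_trace(t, pmin(pmax(ax, -cl), cl), pmin(pmax(ay, -cl), cl),
              pmin(pmax(az, -cl), cl), sample_rate = sr, clip_limit = cl)
}

#' Generate a synthetic nanoparticle size distribution
#'
#' Binned log-normal density with the configured mode and geometric SD,
#' scaled to the configured total concentration (trapezoidal AUC), with
#' multiplicative log-normal bin noise.
#'
#' @param config A [synth_config()]; entries under `particles` are used.
#' @param seed Integer seed.
#' @param mode_nm,gsd,total,noise_sd,dilution Optional overrides.
#' @return A [size_distribution()].
#' @export
gen_size_distribution <- function(config = synth_config(), seed = 1,
                                  mode_nm = NULL, gsd = NULL, total = NULL,
                                  noise_sd = NULL, dilution = NULL) {
  p <- config$particles
  if (!is.null(mode_nm)) p$mode <- mode_nm
  if (!is.null(gsd)) p$gsd <- gsd
  if (!is.null(total)) p$total <- total
  if (!is.null(noise_sd)) p$noise_sd <- noise_sd
  if (!is.null(dilution)) p$dilution <- dilution
  set.seed(.seed_int(seed))
  sl <- log(p$gsd)
  mu <- log(p$mode) + sl^2          # lognormal mode = exp(mu - sl^2)
  dens <- stats::dlnorm(p$bins, mu, sl)
  conc <- dens / .trapz(p$bins, dens) * p$total
  conc <- conc * exp(stats::rnorm(length(conc), 0, p$noise_sd))
  size_distribution(p$bins, conc, dilution_factor = p$dilution)
}

# per-donor, per-transport metric table used to plant metric correlations;
# PTS metrics roughly an order of magnitude above C, log-normal spread
.gen_metrics_table <- function(n_donors, seed) {
  set.seed(.seed_int(seed))
  donors <- sprintf("D%02d", seq_len(n_donors))
  one <- function(mu_c, mu_p, sd) {
    c(exp(stats::rnorm(n_donors, log(mu_c), sd)),
      exp(stats::rnorm(n_donors, log(mu_p), sd)))
  }
  data.frame(
    donor = rep(donors, 2),
    transport = rep(c("C", "PTS"), each = n_donors),
    tk = one(0.015, 0.15, 0.3),
    rms = one(0.2, 1.2, 0.25),
    vdv = one(1.5, 12, 0.3),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic label-free proteome study
#'
#' Log-normal peptide intensities built as protein base level + peptide
#' offset + donor effect + replicate noise, split over two injections;
#' missingness is missing-not-at-random with logistic-in-intensity dropout;
#' a planted set of differential proteins is shifted in PTS samples by a
#' configured log2 effect, and a planted set of metric-correlated proteins
#' varies linearly with the donor/transport VDV (plus noise). The returned
#' truth record lists every planted membership and the generating
#' parameters.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed.
#' @param plasma Plasma types to simulate (default both).
#' @return List: `peptides` (a [peptide_matrix()], linear intensities with
#'   `NA` dropout), `annotation` (annotation table with gene names, classes
#'   and marker labels), `metrics` (per donor/transport transport-metric
#'   table), `truth` (planted memberships, effects, dropout model).
#' @export
gen_proteome <- function(config = synth_config(), seed = 1,
                         plasma = c("PFP", "PPP")) {
  p <- config$proteome
  set.seed(.seed_int(seed))
  donors <- sprintf("D%02d", seq_len(p$n_donors))
  smp <- expand.grid(injection = 1:2, replicate = 1:3,
                     transport = c("C", "PTS"), plasma = plasma,
                     donor = donors, stringsAsFactors = FALSE)
  smp <- smp[, c("donor", "plasma", "transport", "replicate", "injection")]
  ncol_ <- nrow(smp)
  npep <- p$n_proteins * p$peptides_per_protein
  prot_of <- rep(seq_len(p$n_proteins), each = p$peptides_per_protein)
  prot_ids <- sprintf("P%04d", seq_len(p$n_proteins))
  genes <- sprintf("GENE%04d", seq_len(p$n_proteins))

  base <- stats::rnorm(p$n_proteins, p$base_mean, p$base_sd)
  pep_off <- stats::rnorm(npep, -1, p$pep_sd)
  donor_eff <- matrix(stats::rnorm(p$n_proteins * p$n_donors, 0, p$donor_sd),
                      p$n_proteins, p$n_donors,
                      dimnames = list(NULL, donors))
  diff_set <- seq_len(p$n_diff)
  corr_set <- if (p$n_corr > 0) p$n_diff + seq_len(p$n_corr) else integer(0)
  if (p$n_diff + p$n_corr > p$n_proteins)
    stop("planted sets exceed the number of proteins", call. = FALSE)
  metrics <- .gen_metrics_table(p$n_donors, seed + 7777)
  vdv_z <- (log(metrics$vdv) - mean(log(metrics$vdv))) /
    stats::sd(log(metrics$vdv))
  mkey <- paste(metrics$donor, metrics$transport)

  # log2 intensity per peptide x digest (before injection split)
  digest <- unique(smp[, c("donor", "plasma", "transport", "replicate")])
  X <- matrix(NA_real_, npep, nrow(digest))
  for (j in seq_len(nrow(digest))) {
    d <- digest[j, ]
    lvl <- base + donor_eff[, d$donor]
    if (d$transport == "PTS" && p$n_diff > 0)
      lvl[diff_set] <- lvl[diff_set] + p$diff_effect
    if (length(corr_set)) {
      z <- vdv_z[match(paste(d$donor, d$transport), mkey)]
      lvl[corr_set] <- lvl[corr_set] + p$corr_slope * z +
        stats::rnorm(length(corr_set), 0, p$corr_noise)
    }
    X[, j] <- lvl[prot_of] + pep_off +
      stats::rnorm(npep, 0, p$rep_sd)
  }
  # injection split: each injection carries about half the ions
  dkey <- do.call(paste, digest)
  skey <- do.call(paste, smp[, c("donor", "plasma", "transport",
                                 "replicate")])
  jmap <- match(skey, dkey)
  log2_inj <- X[, jmap] - 1 +
    matrix(stats::rnorm(npep * ncol_, 0, p$inj_sd), npep, ncol_)
  # MNAR dropout, logistic-decreasing in log2 intensity
  pmiss <- stats::plogis((p$miss_mid - log2_inj) / p$miss_scale)
  drop <- matrix(stats::runif(npep * ncol_), npep, ncol_) < pmiss
  intensity <- 2^log2_inj
  intensity[drop] <- NA
  colnames(intensity) <- do.call(paste, c(smp, sep = "_"))

  ann <- data.frame(
    protein_id = prot_ids, gene_name = genes,
    has_transmembrane = FALSE,
    subcellular_locations = "", go_cc = "cytoplasm", go_bp = "",
    keywords = "", tissue_specificity = "", description = "",
    cd_marker = NA_character_,
    platelet_set = FALSE, exosome_go = FALSE,
    blood_microparticle_go = FALSE, keratin = FALSE,
    stringsAsFactors = FALSE)

  list(
    peptides = peptide_matrix(intensity, prot_ids[prot_of], smp),
    annotation = ann,
    metrics = metrics,
    truth = list(
      differential = prot_ids[diff_set],
      diff_effect = p$diff_effect,
      metric_correlated = prot_ids[corr_set],
      corr_slope = p$corr_slope,
      miss_mid = p$miss_mid, miss_scale = p$miss_scale,
      expected_missing = mean(pmiss),
      base = stats::setNames(base, prot_ids)
    )
  )
}

#' Generate synthetic blood counts
#'
#' Per-donor red cells (Ec), leukocytes (Lc), lymphocytes (Ly), monocytes
#' (Mc), granulocytes (Gc), platelets (Tc) and hemoglobin (HGB), drawn
#' within the configured physiological ranges; Ec and HGB are coupled
#' through a Gaussian copula at the configured correlation.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed.
#' @return `data.frame`, one row per donor.
#' @export
gen_blood_counts <- function(config = synth_config(), seed = 1) {
  b <- config$blood
  nd <- config$proteome$n_donors
  set.seed(.seed_int(seed))
  donors <- sprintf("D%02d", seq_len(nd))
  z1 <- stats::rnorm(nd)
  z2 <- b$ec_hgb_rho * z1 + sqrt(1 - b$ec_hgb_rho^2) * stats::rnorm(nd)
  to_range <- function(z, rg) rg[1] + stats::pnorm(z) * (rg[2] - rg[1])
  out <- data.frame(donor = donors,
                    Ec = to_range(z1, b$ranges$Ec),
                    HGB = to_range(z2, b$ranges$HGB))
  for (ct in c("Lc", "Ly", "Mc", "Gc", "Tc"))
    out[[ct]] <- stats::runif(nd, b$ranges[[ct]][1], b$ranges[[ct]][2])
  out[, c("donor", "Ec", "Lc", "Ly", "Mc", "Gc", "Tc", "HGB")]
}

#' Generate a complete synthetic study bundle
#'
#' One call produces every input of the pipeline: per-donor carrier and
#' pneumatic-tube traces, per-donor/plasma/transport size distributions,
#' the peptide matrix with annotations and planted truth, and blood counts.
#'
#' @param config A [synth_config()].
#' @param seed Integer master seed; sub-generator seeds are derived from it.
#' @return Named list: `traces` (list `donor.transport` -> trace), `metrics`
#'   (computed transport metrics per trace), `distributions`,
#'   `proteome`, `blood`.
#' @export
gen_study <- function(config = synth_config(), seed = 1) {
  set.seed(.seed_int(seed))
  sub <- sample.int(2^30, 4)
  nd <- config$proteome$n_donors
  donors <- sprintf("D%02d", seq_len(nd))
  traces <- list(); met <- NULL
  for (i in seq_len(nd)) for (tr in c("C", "PTS")) {
    trc <- gen_accel_trace(tr, config, seed = sub[1] + i * 2 +
                             (tr == "PTS"))
    traces[[paste(donors[i], tr, sep = ".")]] <- trc
    m <- summarize_transport(trc, ground_freq = FALSE)
    met <- rbind(met, data.frame(donor = donors[i], transport = tr,
                                 tk = m$tk, rms = m$rms, vdv = m$vdv,
                                 duration = m$duration,
                                 shocks = m$shock_count))
  }
  dists <- list()
  for (i in seq_len(nd)) for (pl in c("PFP", "PPP")) for (tr in c("C", "PTS")) {
    wider <- pl == "PFP" && tr == "PTS"   # transport widens PFP distributions
    dists[[paste(donors[i], pl, tr, sep = ".")]] <-
      gen_size_distribution(config, seed = sub[2] + i * 7 +
                              (pl == "PPP") * 2 + (tr == "PTS"),
                            gsd = if (wider) config$particles$gsd * 1.4
                                  else config$particles$gsd,
                            mode_nm = if (wider) config$particles$mode * 1.2
                                      else config$particles$mode)
  }
  list(traces = traces, metrics = met, distributions = dists,
       proteome = gen_proteome(config, seed = sub[3]),
       blood = gen_blood_counts(config, seed = sub[4]))
}
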