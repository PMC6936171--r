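## Seeded synthetic-study generator. Emulates the field design: 14-point
## 26-h courses sampled every 2 h from 2 h before dawn, 3 pooled biological
## replicates per point, two seasons with realistic subtropical
## photoperiods, truncated-cosine transcript rhythms with the AS/FS
## splicing ratio coupled to ambient temperature, two constant reference
## genes, and lognormal replicate scatter.

#' Build a simulation configuration
#'
#' All defaults mirror the study design the analysis targets; every random
#' draw is derived from `seed` alone.
#'
#' @param seed integer master seed.
#' @param n_replicates biological replicates per time point (default 3).
#' @param noise_sd lognormal sd of replicate scatter (default 0.15).
#' @param ref_noise_sd lognormal sd of reference-gene scatter (default 0.05).
#' @param gain_sd lognormal sd of the per-sample detection gain applied to
#'   peak areas (default 0.2).
#' @param genes data.frame with `gene_id`, `peak_zt`, `amplitude`,
#'   `baseline` for the fully spliced rhythms.
#' @param events data.frame with `event_id`, `gene_id`, `ratio_mean`,
#'   `ratio_amplitude`, `ratio_peak_zt`, `temp_slope` (log10 ratio units
#'   per degree C) describing each AS isoform's splicing-ratio process.
#' @param log_base base of the configured splicing ratio (default 10).
#' @param ref_temp_c reference temperature at which the splicing ratio
#'   equals its configured mean (default 22).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_replicates = 3L, noise_sd = 0.15,
                       ref_noise_sd = 0.05, gain_sd = 0.2,
                       genes = NULL, events = NULL, log_base = 10,
                       ref_temp_c = 22) {
  if (is.null(genes))
    genes <- data.frame(
      gene_id = c("clockA", "clockB"),
      peak_zt = c(5, 8), amplitude = c(100, 80), baseline = c(10, 8),
      stringsAsFactors = FALSE)
  if (is.null(events))
    events <- data.frame(
      event_id = c("I1R", "I5R", "I6R", "I7R"),
      gene_id = c("clockA", "clockA", "clockB", "clockB"),
      ratio_mean = c(-1.0, -1.2, -0.8, -0.9),
      ratio_amplitude = c(0.4, 0.4, 0.3, 0.3),
      ratio_peak_zt = c(22, 22, 5, 5),
      temp_slope = c(-0.05, -0.05, 0, 0),
      stringsAsFactors = FALSE)
  stopifnot(all(genes$amplitude >= 0),
            all(genes$peak_zt >= 0 & genes$peak_zt < 24),
            all(events$gene_id %in% genes$gene_id))
  structure(list(
    seed = as.integer(seed),
    seasons = list(
      winter = photoperiod("winter", "6:30", "18:00"),
      summer = photoperiod("summer", "5:45", "19:00")),
    organs_by_season = list(winter = "L1", summer = c("L1", "I1", "I5")),
    schedule = list(start_offset = 2, interval = 2, duration = 26),
    n_replicates = as.integer(n_replicates),
    genes = genes, events = events,
    reference_genes = data.frame(
      gene_id = c("refGAPDH", "refPP2AA2"), level = c(500, 300),
      stringsAsFactors = FALSE),
    noise_sd = noise_sd, ref_noise_sd = ref_noise_sd, gain_sd = gain_sd,
    log_base = log_base, ref_temp_c = ref_temp_c,
    temperature = list(
      mean_c = c(winter = 18, summer = 26),
      diel_amplitude_c = c(winter = 4, summer = 5),
      warmest_clock_time = 14,
      ar1_phi = 0.6, ar1_sd = 0.5, log_interval_h = 1)),
    class = "sim_config")
}

## Sharp-peaked diel waveform: cosine truncated at zero.
truncated_cosine <- function(zt, peak_zt) {
  pmax(0, cos(2 * pi * (zt - peak_zt) / 24))
}

#' Simulate ambient temperature logs
#'
#' One series per season: seasonal mean plus a diel cosine (warmest
#' mid-afternoon) plus AR(1) noise, logged at a fixed interval over a span
#' covering the whole sampling course.
#'
#' @param cfg a [sim_config()].
#' @return data.frame with `season_id`, `clock_time` (decimal hours from
#'   midnight of the first day, increasing past 24) and `temp_c`.
#' @export
simulate_temperature <- function(cfg) {
  tp <- cfg$temperature
  out <- lapply(seq_along(cfg$seasons), function(si) {
    pp <- cfg$seasons[[si]]
    season <- pp$season_id
    grid <- seq(floor(pp$dawn) - 6, ceiling(pp$dawn) + 32,
                by = tp$log_interval_h)
    base <- tp$mean_c[[season]] +
      tp$diel_amplitude_c[[season]] *
        cos(2 * pi * (grid - tp$warmest_clock_time) / 24)
    ar <- withr::with_seed(cfg$seed + 101L * si, {
      innov_sd <- tp$ar1_sd * sqrt(1 - tp$ar1_phi^2)
      as.numeric(stats::arima.sim(list(ar = tp$ar1_phi), n = length(grid),
                                  sd = innov_sd))
    })
    data.frame(season_id = season, clock_time = grid, temp_c = base + ar,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate a complete study's isoform abundances
#'
#' Fully spliced transcripts follow truncated-cosine diel rhythms; each AS
#' isoform is derived from its FS level through a log splicing ratio with a
#' mean, a diel rhythmic term and a temperature coupling:
#' `log10(AS/FS) = mean + amplitude * cos(2*pi*(zt - peak)/24) +
#' slope * (temp - ref_temp)`. Replicates scatter lognormally around the
#' truth. The truth table records every generating value.
#'
#' @param cfg a [sim_config()].
#' @return List with `samples` (metadata: one row per sample pool),
#'   `abundances` (one row per sample x isoform, noisy `abundance` plus
#'   `true_abundance`), `truth` (per sample x event: `log_ratio_true`,
#'   `temp_c`, generating parameters) and `temperature` (the simulated
#'   logs).
#' @export
simulate_abundances <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  temps <- simulate_temperature(cfg)
  meta <- list(); k <- 0L
  for (si in seq_along(cfg$seasons)) {
    pp <- cfg$seasons[[si]]
    sched <- sampling_schedule(pp, cfg$schedule$start_offset,
                               cfg$schedule$interval, cfg$schedule$duration)
    st <- temps[temps$season_id == pp$season_id, ]
    for (organ in cfg$organs_by_season[[pp$season_id]]) {
      for (i in seq_len(nrow(sched))) {
        for (r in seq_len(cfg$n_replicates)) {
          k <- k + 1L
          meta[[k]] <- data.frame(
            sample_id = sprintf("%s_%s_T%02d_r%d", pp$season_id, organ,
                                sched$point[i], r),
            season_id = pp$season_id, organ = organ,
            point = sched$point[i], clock_time = sched$clock_time[i],
            T = sched$T[i], zt = sched$zt[i],
            day_index = sched$day_index[i], replicate = r,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  samples <- do.call(rbind, meta)
  samples$temp_c <- NA_real_
  for (season in names(cfg$seasons)) {
    st <- temps[temps$season_id == season, ]
    sel <- samples$season_id == season
    samples$temp_c[sel] <- temperature_at(
      st[, c("clock_time", "temp_c")], samples$clock_time[sel])
  }

  ## true levels per sample x isoform
  ab <- list(); tr <- list(); k <- 0L; kt <- 0L
  for (g in seq_len(nrow(cfg$genes))) {
    gene <- cfg$genes[g, ]
    fs_true <- gene$baseline +
      gene$amplitude * truncated_cosine(samples$zt, gene$peak_zt)
    k <- k + 1L
    ab[[k]] <- data.frame(sample_id = samples$sample_id,
                          gene_id = gene$gene_id, isoform_id = "FS",
                          true_abundance = fs_true,
                          stringsAsFactors = FALSE)
    evs <- cfg$events[cfg$events$gene_id == gene$gene_id, , drop = FALSE]
    for (e in seq_len(nrow(evs))) {
      ev <- evs[e, ]
      r_true <- ev$ratio_mean +
        ev$ratio_amplitude *
          cos(2 * pi * (samples$zt - ev$ratio_peak_zt) / 24) +
        ev$temp_slope * (samples$temp_c - cfg$ref_temp_c)
      k <- k + 1L
      ab[[k]] <- data.frame(sample_id = samples$sample_id,
                            gene_id = gene$gene_id, isoform_id = ev$event_id,
                            true_abundance = fs_true * cfg$log_base^r_true,
                            stringsAsFactors = FALSE)
      kt <- kt + 1L
      tr[[kt]] <- data.frame(sample_id = samples$sample_id,
                             gene_id = gene$gene_id,
                             event_id = ev$event_id,
                             zt = samples$zt, temp_c = samples$temp_c,
                             log_ratio_true = r_true,
                             temp_slope = ev$temp_slope,
                             ratio_peak_zt = ev$ratio_peak_zt,
                             stringsAsFactors = FALSE)
    }
  }
  for (rg in seq_len(nrow(cfg$reference_genes))) {
    k <- k + 1L
    ab[[k]] <- data.frame(sample_id = samples$sample_id,
                          gene_id = cfg$reference_genes$gene_id[rg],
                          isoform_id = "FS",
                          true_abundance = cfg$reference_genes$level[rg],
                          stringsAsFactors = FALSE)
  }
  abundances <- do.call(rbind, ab)
  is_ref <- abundances$gene_id %in% cfg$reference_genes$gene_id
  noise <- withr::with_seed(cfg$seed + 7L, {
    sdlog <- ifelse(is_ref, cfg$ref_noise_sd, cfg$noise_sd)
    stats::rlnorm(nrow(abundances), meanlog = 0, sdlog = sdlog)
  })
  abundances$abundance <- abundances$true_abundance * noise
  rownames(abundances) <- NULL
  list(samples = samples, abundances = abundances,
       truth = do.call(rbind, tr), temperature = temps)
}

#' Default amplicon panel for the synthetic study
#'
#' Expected amplicon sizes within the assay's working range; each AS
#' isoform's size differs from its gene's FS amplicon by the retained
#' length implied by the event. Two reference-gene amplicons included.
#'
#' @param cfg a [sim_config()].
#' @return data.frame with `gene_id`, `isoform_id`, `expected_size`.
#' @export
default_panel <- function(cfg) {
  data.frame(
    gene_id = c("clockA", "clockA", "clockA", "clockB", "clockB",
                "clockB", "refGAPDH", "refPP2AA2"),
    isoform_id = c("FS", "I1R", "I5R", "FS", "I6R", "I7R", "FS", "FS"),
    expected_size = c(304, 385, 392, 450, 540, 535, 242, 260),
    stringsAsFactors = FALSE)
}

## Quadratic (slightly non-linear, strictly monotone) migration model used
## by the simulator; sizing code never sees it.
sim_migration <- function(bp) 800 + 3.6 * bp - 0.0012 * bp^2

#' Simulate GeneMapper-style peak tables
#'
#' Per sample: ladder peaks at the size standard's known fragment sizes and
#' one target peak per panel amplicon, with areas proportional to the
#' simulated abundance times a per-sample lognormal gain. Migrations follow
#' a quadratic mobility model unknown to the sizing code.
#'
#' @param sim output of [simulate_abundances()].
#' @param panel amplicon panel, e.g. [default_panel()].
#' @param cfg the [sim_config()] used for `sim`.
#' @param area_scale RFU-scan units per abundance unit (default 100).
#' @return data.frame with `sample_id`, `dye` (`"ladder"`/`"target"`),
#'   `migration`, `size_known` (ladder rows only), `height`, `area`.
#' @export
simulate_peak_tables <- function(sim, panel, cfg, area_scale = 100) {
  if (nrow(panel) == 0L) stop("empty amplicon panel")
  need <- unique(sim$abundances[, c("gene_id", "isoform_id")])
  have <- paste(panel$gene_id, panel$isoform_id)
  if (!all(paste(need$gene_id, need$isoform_id) %in% have))
    stop("panel does not cover all simulated isoforms")
  ladder_bp <- c(35, 50, 75, 100, 139, 150, 160, 200, 250, 300, 340, 350,
                 400, 450, 490, 500, 550, 600, 650, 700, 750, 800, 850)
  samples <- unique(sim$abundances$sample_id)
  gains <- withr::with_seed(cfg$seed + 13L, {
    stats::setNames(stats::rlnorm(length(samples), 0, cfg$gain_sd), samples)
  })
  idx <- match(paste(sim$abundances$gene_id, sim$abundances$isoform_id),
               have)
  tgt <- data.frame(
    sample_id = sim$abundances$sample_id, dye = "target",
    migration = sim_migration(panel$expected_size[idx]),
    size_known = NA_real_,
    area = sim$abundances$abundance * area_scale *
      gains[sim$abundances$sample_id],
    stringsAsFactors = FALSE)
  tgt$height <- tgt$area / 10
  lad <- data.frame(
    sample_id = rep(samples, each = length(ladder_bp)), dye = "ladder",
    migration = rep(sim_migration(ladder_bp), length(samples)),
    size_known = rep(ladder_bp, length(samples)),
    area = 50, height = 5, stringsAsFactors = FALSE)
  out <- rbind(lad[, c("sample_id", "dye", "migration", "size_known",
                       "height", "area")],
               tgt[, c("sample_id", "dye", "migration", "size_known",
                       "height", "area")])
  out <- out[order(out$sample_id, out$dye, out$migration), ]
  rownames(out) <- NULL
  out
}
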