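# Seeded synthetic-data generators with recorded ground truth.
#
# Each generator draws all randomness inside withr::with_seed(), so identical
# config + seed reproduces output bitwise and the caller's RNG state is left
# untouched.

#' Simulation configuration for a DNA-fibre sister-fork population
#'
#' Defines the experimental regime emulated by [sim_fibre_population()]:
#' a population of replication origins, each firing two sister forks whose
#' per-arm speeds are drawn independently from
#' `Normal(mean_speed, speed_sd)` (truncated at a small positive floor).
#' A pair stalls with probability `stall_prob`; a stalled pair has one
#' uniformly chosen arm shortened by the factor `1 - stall_severity`,
#' producing sister asymmetry. Tract lengths follow the fibre conversion
#' `length_um = speed * pulse / kb_per_um`.
#'
#' @param n_tracks Number of origins (sister-fork pairs).
#' @param mean_speed Mean fork speed, kb/min.
#' @param speed_sd Between-arm speed SD, kb/min.
#' @param stall_prob Probability a pair contains a stalled fork.
#' @param stall_severity Fraction of the stalled arm lost, in `(0, 1)`.
#' @param pulse_min_first,pulse_min_second Durations of the two analogue
#'   pulses, minutes (20/20 emulates the usual CldU/IdU regime).
#' @param kb_per_um Conversion factor used to lay the tracts down, kb/um.
#' @param seed Integer RNG seed.
#' @return A classed config list for [sim_fibre_population()].
#' @export
fibre_sim_config <- function(n_tracks = 200, mean_speed = 1.5, speed_sd = 0.15,
                             stall_prob = 0, stall_severity = 0.5,
                             pulse_min_first = 20, pulse_min_second = 20,
                             kb_per_um = 2.59, seed = 1L) {
  stopifnot(n_tracks >= 0, mean_speed > 0, speed_sd >= 0,
            stall_prob >= 0, stall_prob <= 1,
            stall_severity > 0, stall_severity < 1,
            pulse_min_first > 0, pulse_min_second > 0, kb_per_um > 0)
  structure(as.list(environment()), class = "fibre_sim_config")
}

#' Simulate a sister-fork pair population with ground-truth stalls
#'
#' @param cfg A [fibre_sim_config()].
#' @return List with `pairs` (one row per origin: `origin_id`, `left_um`,
#'   `right_um`, `pulse_min`, true per-arm speeds `speed_left`,
#'   `speed_right` in kb/min, and ground truth `stalled`,
#'   `stalled_arm` in `{"left","right",NA}`) and `tracks`
#'   (per-fork two-pulse measurements: `track_id`, `first_len_um`,
#'   `second_len_um`, `first_pulse_min`, `second_pulse_min`, `true_speed`).
#' @export
sim_fibre_population <- function(cfg) {
  stopifnot(inherits(cfg, "fibre_sim_config"))
  n <- cfg$n_tracks
  if (n == 0L) {
    empty <- data.frame(origin_id = character(), left_um = numeric(),
                        right_um = numeric(), pulse_min = numeric(),
                        speed_left = numeric(), speed_right = numeric(),
                        stalled = logical(), stalled_arm = character())
    return(list(pairs = empty, tracks = data.frame()))
  }
  withr::with_seed(cfg$seed, {
    sp_l <- pmax(stats::rnorm(n, cfg$mean_speed, cfg$speed_sd), 1e-3)
    sp_r <- pmax(stats::rnorm(n, cfg$mean_speed, cfg$speed_sd), 1e-3)
    stalled <- stats::runif(n) < cfg$stall_prob
    side <- ifelse(stats::runif(n) < 0.5, "left", "right")
    side[!stalled] <- NA_character_
    len_l <- sp_l * cfg$pulse_min_second / cfg$kb_per_um
    len_r <- sp_r * cfg$pulse_min_second / cfg$kb_per_um
    shrink <- 1 - cfg$stall_severity
    len_l <- ifelse(stalled & side == "left",  len_l * shrink, len_l)
    len_r <- ifelse(stalled & side == "right", len_r * shrink, len_r)
    first_l <- sp_l * cfg$pulse_min_first / cfg$kb_per_um
    first_r <- sp_r * cfg$pulse_min_first / cfg$kb_per_um
    pairs <- data.frame(
      origin_id = sprintf("origin_%04d", seq_len(n)),
      left_um = len_l, right_um = len_r,
      pulse_min = cfg$pulse_min_second,
      speed_left = sp_l, speed_right = sp_r,
      stalled = stalled, stalled_arm = side)
    tracks <- data.frame(
      track_id = sprintf("fork_%04d_%s", rep(seq_len(n), each = 2),
                         rep(c("L", "R"), n)),
      first_len_um = as.vector(rbind(first_l, first_r)),
      second_len_um = as.vector(rbind(len_l, len_r)),
      first_pulse_min = cfg$pulse_min_first,
      second_pulse_min = cfg$pulse_min_second,
      true_speed = as.vector(rbind(sp_l, sp_r)))
    list(pairs = pairs, tracks = tracks)
  })
}

#' Simulation configuration for a two-channel 3D puncta volume
#'
#' Defines the nuclear-puncta regime emulated by [sim_two_channel_volume()]:
#' spherical objects of constant interior intensity placed without
#' wrap-around in two channels (A, e.g. a remodeller stain; B, e.g. an
#' RNA:DNA-hybrid stain). A fraction `coloc_fraction` of B objects is
#' centred inside an A object (guaranteeing at least one shared voxel);
#' the remainder are kept far enough from every A object that no voxel is
#' shared. Same-channel objects are mutually separated so segmentation
#' recovers them one-to-one.
#'
#' @param shape Integer length-3 vector, voxels per axis.
#' @param voxel_size Numeric length-3, micrometres per voxel along each axis.
#' @param n_objects_a,n_objects_b Object counts per channel.
#' @param coloc_fraction Probability a B object colocalizes with A.
#' @param radius_min,radius_max Object radius range, voxels.
#' @param intensity_mean,intensity_sd Interior intensity distribution, a.u.
#' @param noise_sd Additive Gaussian voxel noise, a.u.
#' @param max_tries Placement retries per object before a placement error.
#' @param seed Integer RNG seed.
#' @return A classed config list for [sim_two_channel_volume()].
#' @export
volume_sim_config <- function(shape = c(64L, 64L, 64L),
                              voxel_size = c(0.05, 0.05, 0.15),
                              n_objects_a = 50, n_objects_b = 50,
                              coloc_fraction = 0.5,
                              radius_min = 2, radius_max = 2.6,
                              intensity_mean = 100, intensity_sd = 10,
                              noise_sd = 2, max_tries = 5000L, seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape > 0),
            length(voxel_size) == 3L, all(voxel_size > 0),
            n_objects_a >= 0, n_objects_b >= 0,
            coloc_fraction >= 0, coloc_fraction <= 1,
            radius_min >= 1, radius_max >= radius_min,
            intensity_mean > 0, noise_sd >= 0)
  structure(as.list(environment()), class = "volume_sim_config")
}

# Paint a constant-intensity sphere into `vol`; returns the modified array.
.paint_sphere <- function(vol, centre, radius, intensity) {
  dims <- dim(vol)
  rng <- lapply(1:3, function(k)
    max(1L, floor(centre[k] - radius)):min(dims[k], ceiling(centre[k] + radius)))
  gx <- rng[[1]]; gy <- rng[[2]]; gz <- rng[[3]]
  dx2 <- (gx - centre[1])^2
  dy2 <- (gy - centre[2])^2
  dz2 <- (gz - centre[3])^2
  d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  sel <- d2 <= radius^2
  sub <- vol[gx, gy, gz, drop = FALSE]
  sub[sel] <- sub[sel] + intensity
  vol[gx, gy, gz] <- sub
  vol
}

#' Simulate a registered two-channel 3D volume with known colocalization
#'
#' @param cfg A [volume_sim_config()].
#' @return List with `channel_a`, `channel_b` (3D intensity arrays),
#'   `voxel_size`, and `truth` (one row per object: `channel`, `object_id`,
#'   centre coordinates in voxels, `radius`, `intensity`, and for channel B
#'   the ground-truth logical `coloc`).
#' @export
sim_two_channel_volume <- function(cfg) {
  stopifnot(inherits(cfg, "volume_sim_config"))
  dims <- as.integer(cfg$shape)
  sep_same <- 2 * cfg$radius_max + 3     # same-channel objects stay distinct
  sep_apart <- 2 * cfg$radius_max + 2    # non-coloc B shares no voxel with A
  off_max <- max(cfg$radius_min - 1, 0.5)  # coloc B centre offset inside host
  # A objects spaced so that B puncta centred in distinct hosts are
  # themselves separated by at least sep_same
  sep_a <- sep_same + 2 * off_max + 0.5
  withr::with_seed(cfg$seed, {
    place <- function(existing, min_dist, avoid = NULL, avoid_dist = 0) {
      margin <- cfg$radius_max + 2
      for (i in seq_len(cfg$max_tries)) {
        p <- stats::runif(3, min = margin, max = dims - margin)
        ok <- TRUE
        if (nrow(existing) > 0)
          ok <- all(sqrt(colSums((t(existing) - p)^2)) >= min_dist)
        if (ok && !is.null(avoid) && nrow(avoid) > 0)
          ok <- all(sqrt(colSums((t(avoid) - p)^2)) >= avoid_dist)
        if (ok) return(p)
      }
      stop("placement error: could not place object after ", cfg$max_tries,
           " tries; reduce object count or separation")
    }
    rad <- function() stats::runif(1, cfg$radius_min, cfg$radius_max)
    inten <- function() max(stats::rnorm(1, cfg$intensity_mean, cfg$intensity_sd),
                            cfg$intensity_mean / 10)

    ca <- array(0, dims); cb <- array(0, dims)
    centres_a <- matrix(numeric(), 0, 3)
    truth <- list()
    for (i in seq_len(cfg$n_objects_a)) {
      p <- place(centres_a, sep_a)
      centres_a <- rbind(centres_a, p)
      r <- rad(); v <- inten()
      ca <- .paint_sphere(ca, p, r, v)
      truth[[length(truth) + 1L]] <- data.frame(
        channel = "A", object_id = sprintf("A_%03d", i),
        x = p[1], y = p[2], z = p[3], radius = r, intensity = v, coloc = NA)
    }
    centres_b <- matrix(numeric(), 0, 3)
    coloc <- if (cfg$n_objects_b > 0)
      stats::runif(cfg$n_objects_b) < cfg$coloc_fraction & cfg$n_objects_a > 0
    else logical()
    host_order <- if (cfg$n_objects_a > 0) sample.int(cfg$n_objects_a)
                  else integer()
    n_hosted <- 0L
    # colocalized B objects are placed first, in distinct hosts while any
    # remain, so the A-object spacing already enforces the B-B separation;
    # free B objects then avoid everything placed so far
    centre_b <- matrix(NA_real_, cfg$n_objects_b, 3)
    for (i in which(coloc)) {
      for (try in seq_len(cfg$max_tries)) {
        host_idx <- if (n_hosted < length(host_order))
          host_order[n_hosted + 1L]
        else sample.int(nrow(centres_a), 1L)
        host <- centres_a[host_idx, ]
        off_r <- off_max * stats::runif(1)^(1 / 3)
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        p <- host + off_r * u   # centre inside host sphere: >= 1 shared voxel
        ok <- nrow(centres_b) == 0 ||
          all(sqrt(colSums((t(centres_b) - p)^2)) >= sep_same)
        if (ok) { n_hosted <- n_hosted + 1L; break }
        if (try == cfg$max_tries) stop("placement error for colocalized object")
      }
      centres_b <- rbind(centres_b, p)
      centre_b[i, ] <- p
    }
    for (i in which(!coloc)) {
      p <- place(centres_b, sep_same, avoid = centres_a, avoid_dist = sep_apart)
      centres_b <- rbind(centres_b, p)
      centre_b[i, ] <- p
    }
    for (i in seq_len(cfg$n_objects_b)) {
      r <- rad(); v <- inten()
      p <- centre_b[i, ]
      cb <- .paint_sphere(cb, p, r, v)
      truth[[length(truth) + 1L]] <- data.frame(
        channel = "B", object_id = sprintf("B_%03d", i),
        x = p[1], y = p[2], z = p[3], radius = r, intensity = v,
        coloc = coloc[i])
    }
    if (cfg$noise_sd > 0) {
      ca <- ca + array(stats::rnorm(prod(dims), 0, cfg$noise_sd), dims)
      cb <- cb + array(stats::rnorm(prod(dims), 0, cfg$noise_sd), dims)
    }
    list(channel_a = ca, channel_b = cb, voxel_size = cfg$voxel_size,
         truth = do.call(rbind, truth))
  })
}

#' Simulation configuration for a tethered-locus intensity trace
#'
#' Defines the live-imaging regime emulated by [sim_locus_trace()]: a latent
#' R-loop count at a tagged locus follows an immigration-death (birth-death)
#' process observed every `dt_min` minutes through its exact one-step
#' transition, `N(t+dt) = Binomial(N(t), exp(-mu dt)) +
#' Poisson(lambda/mu (1 - exp(-mu dt)))` (Binomial survival thinning, not
#' an Euler step), whose stationary mean is exactly `lambda/mu` — the
#' M/M/infinity law. The reporter channel reads
#' `gain * N + noise` (floored at 1e-6 so ratios stay defined); the
#' normalizer channel is constant plus noise. Defaults follow the usual
#' 6-min / 1500-min time-lapse regime; the kinetic rates themselves are
#' illustrative, not fitted to any dataset.
#'
#' @param duration_min Total imaging time, minutes.
#' @param dt_min Sampling interval, minutes.
#' @param formation_rate R-loop formation rate, events/min.
#' @param resolution_rate Per-R-loop resolution rate, /min.
#' @param n0 Initial R-loop count.
#' @param reporter_gain Reporter intensity units per R-loop.
#' @param reporter_noise_sd,normalizer_mean,normalizer_noise_sd Intensity
#'   units (a.u.).
#' @param seed Integer RNG seed.
#' @return A classed config list for [sim_locus_trace()].
#' @export
kinetics_sim_config <- function(duration_min = 1500, dt_min = 6,
                                formation_rate = 0.5, resolution_rate = 0.01,
                                n0 = 50L, reporter_gain = 1,
                                reporter_noise_sd = 0.5, normalizer_mean = 100,
                                normalizer_noise_sd = 1, seed = 1L) {
  stopifnot(formation_rate >= 0, resolution_rate >= 0, dt_min > 0,
            duration_min >= dt_min, n0 >= 0, reporter_gain > 0,
            reporter_noise_sd >= 0, normalizer_mean > 0,
            normalizer_noise_sd >= 0)
  structure(as.list(environment()), class = "kinetics_sim_config")
}

#' Simulate a locus reporter/normalizer trace with its latent count path
#'
#' @param cfg A [kinetics_sim_config()].
#' @return List with `trace` (`t_min`, `reporter`, `normalizer`) and
#'   `latent` (`t_min`, `n` — the integer R-loop count path).
#' @export
sim_locus_trace <- function(cfg) {
  stopifnot(inherits(cfg, "kinetics_sim_config"))
  t <- seq(0, cfg$duration_min, by = cfg$dt_min)
  k <- length(t)
  withr::with_seed(cfg$seed, {
    n <- integer(k)
    n[1] <- as.integer(cfg$n0)
    p_surv <- exp(-cfg$resolution_rate * cfg$dt_min)
    # exact one-step transition of the immigration-death process: standing
    # R-loops are thinned by the survival probability, and arrivals within
    # the interval are already thinned for their own partial exposure, so
    # the chain has stationary mean formation/resolution exactly
    mean_born <- if (cfg$resolution_rate > 0)
      cfg$formation_rate / cfg$resolution_rate * (1 - p_surv)
    else cfg$formation_rate * cfg$dt_min
    for (i in seq_len(k - 1L)) {
      born <- stats::rpois(1L, mean_born)
      survived <- stats::rbinom(1L, n[i], p_surv)
      n[i + 1L] <- survived + born
    }
    reporter <- pmax(cfg$reporter_gain * n +
                       stats::rnorm(k, 0, cfg$reporter_noise_sd), 1e-6)
    normalizer <- pmax(cfg$normalizer_mean +
                         stats::rnorm(k, 0, cfg$normalizer_noise_sd), 1e-6)
    list(trace = data.frame(t_min = t, reporter = reporter,
                            normalizer = normalizer),
         latent = data.frame(t_min = t, n = n))
  })
}

#' Simulation configuration for a confounded gene/peak co-enrichment table
#'
#' Defines the regime emulated by [sim_gene_peak_table()]: two genomic
#' signals (a remodeller ChIP-seq peak count and an R-loop DRIP-seq peak
#' count per gene body) that are both driven by gene expression
#' (`expression_effect`) and, optionally, by a shared direct-association
#' latent factor (`direct_association`). Counts are Poisson (with optional
#' gamma overdispersion) around a rate linear in expression,
#' `rate = max(expression_effect * e + direct_association * u, 0)`, so with
#' `direct_association = 0` the two count signals are conditionally
#' independent given expression with a conditional mean linear in it:
#' their pairwise correlation is positive while the population partial
#' correlation given expression is exactly zero.
#'
#' @param n_genes Number of genes (`>= 4`).
#' @param expression_effect Slope of the Poisson rate on expression.
#' @param direct_association Slope of the rate on the shared latent factor.
#' @param noise_sd Extra-Poisson noise: coefficient of variation of an
#'   independent per-gene, per-signal gamma rate multiplier (0 = pure
#'   Poisson).
#' @param n_states Number of chromatin states in the toy segmentation.
#' @param gene_length,gene_gap Gene body and intergenic sizes, bp.
#' @param peak_width Peak size, bp (200 matches ChromHMM-style binning).
#' @param seed Integer RNG seed.
#' @return A classed config list for [sim_gene_peak_table()].
#' @export
genomics_sim_config <- function(n_genes = 500, expression_effect = 0.4,
                                direct_association = 1, noise_sd = 0.3,
                                n_states = 8, gene_length = 6000L,
                                gene_gap = 400L, peak_width = 200L, seed = 1L) {
  stopifnot(n_genes >= 4, n_states >= 2, noise_sd >= 0,
            gene_length >= peak_width, gene_gap >= 0, peak_width > 0)
  structure(as.list(environment()), class = "genomics_sim_config")
}

#' Simulate per-gene peak counts, toy peak BEDs and a state segmentation
#'
#' @param cfg A [genomics_sim_config()].
#' @return List with `genes` (`gene_id`, `chrom`, `start`, `end`,
#'   `expression`, `ino80_abundance`, `drip_abundance` — 0-based half-open
#'   coordinates), `peaks_ino80` / `peaks_drip` (BED-style data frames whose
#'   per-gene peak counts equal the abundances), `states` (4-column
#'   BED-style segmentation partitioning the toy genome, labels
#'   `"state_1"..`), `genome_length`, and `truth` (the latent shared factor
#'   `u` plus the generating coefficients).
#' @export
sim_gene_peak_table <- function(cfg) {
  stopifnot(inherits(cfg, "genomics_sim_config"))
  n <- cfg$n_genes
  pitch <- cfg$gene_length + cfg$gene_gap
  genome_len <- n * pitch
  max_peaks <- cfg$gene_length %/% cfg$peak_width
  withr::with_seed(cfg$seed, {
    expr <- stats::rlnorm(n, meanlog = 2, sdlog = 0.7)
    u <- stats::rnorm(n)
    rate <- pmax(cfg$expression_effect * expr + cfg$direct_association * u, 0)
    mk_counts <- function() {
      disp <- if (cfg$noise_sd > 0)
        stats::rgamma(n, shape = 1 / cfg$noise_sd^2, scale = cfg$noise_sd^2)
      else 1
      pmin(stats::rpois(n, rate * disp), max_peaks)
    }
    ino80 <- mk_counts()
    drip <- mk_counts()
    gstart <- (seq_len(n) - 1L) * pitch
    genes <- data.frame(gene_id = sprintf("gene_%05d", seq_len(n)),
                        chrom = "chrS", start = gstart,
                        end = gstart + cfg$gene_length,
                        expression = expr,
                        ino80_abundance = ino80, drip_abundance = drip)
    mk_peaks <- function(counts) {
      idx <- rep(seq_len(n), counts)
      off <- unlist(lapply(counts, function(k) seq_len(k) - 1L), use.names = FALSE)
      if (length(idx) == 0L)
        return(data.frame(chrom = character(), start = integer(),
                          end = integer()))
      s <- gstart[idx] + off * cfg$peak_width
      data.frame(chrom = "chrS", start = s, end = s + cfg$peak_width)
    }
    # random segmentation: contiguous blocks, every state represented
    n_iv <- max(cfg$n_states * 3L, 12L)
    cuts <- sort(sample.int(genome_len - 1L, n_iv - 1L))
    bounds <- c(0L, cuts, genome_len)
    labels <- c(seq_len(cfg$n_states),
                sample.int(cfg$n_states, n_iv - cfg$n_states, replace = TRUE))
    labels <- sample(labels)
    states <- data.frame(chrom = "chrS", start = bounds[-length(bounds)],
                         end = bounds[-1],
                         state = sprintf("state_%d", labels))
    list(genes = genes, peaks_ino80 = mk_peaks(ino80),
         peaks_drip = mk_peaks(drip), states = states,
         genome_length = genome_len,
         truth = list(u = u, expression_effect = cfg$expression_effect,
                      direct_association = cfg$direct_association))
  })
}

#' Simulate a growth plate under a multiplicative epistasis model
#'
#' Emulates a two-perturbation proliferation experiment: single-condition
#' wells grow at fractions `effect_a` and `effect_b` of control, and
#' combined-condition wells at `effect_a * effect_b * interaction` plus
#' well-to-well Gaussian noise. `interaction = 1` encodes the multiplicative
#' independence null; values above 1 encode rescue.
#'
#' @param effect_a,effect_b Single-perturbation growth fractions, in
#'   `(0, 1.5]`.
#' @param interaction Multiplicative deviation from independence (1 = null).
#' @param n_wells Wells per condition (`>= 1`).
#' @param noise_sd Well-to-well SD of combined-condition growth (fraction).
#' @param seed Integer RNG seed.
#' @return `data.frame` with `well`, `condition`
#'   (`control`/`a`/`b`/`combined`) and `growth` (fraction of control),
#'   plus attribute `truth` recording the generating parameters.
#' @export
sim_growth_plate <- function(effect_a, effect_b, interaction = 1,
                             n_wells = 6L, noise_sd = 0, seed = 1L) {
  stopifnot(effect_a > 0, effect_a <= 1.5, effect_b > 0, effect_b <= 1.5,
            interaction > 0, noise_sd >= 0)
  if (n_wells < 1) stop("n_wells must be >= 1")
  withr::with_seed(seed, {
    combined <- pmax(effect_a * effect_b * interaction +
                       stats::rnorm(n_wells, 0, noise_sd), 0)
    out <- data.frame(
      well = sprintf("w%02d", seq_len(4L * n_wells)),
      condition = rep(c("control", "a", "b", "combined"), each = n_wells),
      growth = c(rep(1, n_wells), rep(effect_a, n_wells),
                 rep(effect_b, n_wells), combined))
    attr(out, "truth") <- list(effect_a = effect_a, effect_b = effect_b,
                               interaction = interaction, noise_sd = noise_sd)
    out
  })
}
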