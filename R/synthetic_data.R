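# Seeded synthetic-data generators: diet-class MA profiles, parametric
# mandible configurations realizing a target profile, fragmented
# "fossil" replicates, pure-birth trees and Brownian-motion traits, and
# a full study bundle mirroring a comparative mandible dataset.
#
# Default diet-class profiles encode the qualitative pattern the
# ordination is meant to recover: herbivores bite with comparatively
# high MA falling almost linearly toward the incisivi, carnivores sit at
# the low end of the MA range with a gently exponential decrease, and
# omnivores are intermediate.

.diet_defaults <- list(
  herbivore = list(level = 0.60, shape = "linear",      curvature = 0.4),
  omnivore  = list(level = 0.45, shape = "exponential", curvature = 0.8),
  carnivore = list(level = 0.30, shape = "exponential", curvature = 1.5))

#' Diet-class MA profile specification
#'
#' @param diet_class `"herbivore"`, `"omnivore"` or `"carnivore"`;
#'   selects the class defaults, each overridable.
#' @param level Vertical position of the curve (MA at the proximal end
#'   for the linear shape; the scale of the exponential component).
#' @param shape `"linear"` (`ma(s) = level (1 - curvature s)`) or
#'   `"exponential"` (`ma(s) = level exp(-curvature s) + floor`).
#' @param curvature Non-negative decay/slope parameter.
#' @param floor Additive offset of the exponential shape (default 0.1).
#' @param noise_sd Isotropic landmark noise used when a mandible is
#'   generated from the profile.
#' @param tooth_amplitude Relative amplitude of quasi-periodic dental
#'   (incisivus/molar) relief superimposed on the profile as
#'   `ma(s) * (1 + a sin(2 pi n_teeth s + phase))`; 0 (default)
#'   disables it.
#' @param n_teeth Number of tooth cycles along the edge.
#' @param tooth_phase Phase of the dental relief (radians).
#' @return An object of class `diet_profile`.
#' @export
diet_profile <- function(diet_class = c("herbivore", "omnivore",
                                        "carnivore"),
                         level = NULL, shape = NULL, curvature = NULL,
                         floor = 0.1, noise_sd = 0,
                         tooth_amplitude = 0, n_teeth = 10L,
                         tooth_phase = 0) {
  diet_class <- match.arg(diet_class)
  def <- .diet_defaults[[diet_class]]
  spec <- list(diet_class = diet_class,
               level = if (is.null(level)) def$level else level,
               shape = if (is.null(shape)) def$shape else
                 match.arg(shape, c("linear", "exponential")),
               curvature = if (is.null(curvature)) def$curvature else
                 curvature,
               floor = floor, noise_sd = noise_sd,
               tooth_amplitude = tooth_amplitude,
               n_teeth = as.integer(n_teeth), tooth_phase = tooth_phase)
  if (spec$level <= 0) stop("level must be positive")
  if (spec$curvature < 0) stop("curvature must be non-negative")
  if (spec$noise_sd < 0) stop("noise_sd must be non-negative")
  if (spec$tooth_amplitude < 0 || spec$tooth_amplitude >= 1)
    stop("tooth_amplitude must be in [0, 1)")
  structure(spec, class = "diet_profile")
}

#' Target MA profile function of a diet specification
#'
#' @param spec A [diet_profile].
#' @return A vectorised function `s -> ma(s)`, strictly positive on
#'   `[0, 1]` (an error is raised otherwise).
#' @export
target_ma_profile <- function(spec) {
  stopifnot(inherits(spec, "diet_profile"))
  base <- if (spec$shape == "linear") {
    function(s) spec$level * (1 - spec$curvature * s)
  } else {
    function(s) spec$level * exp(-spec$curvature * s) + spec$floor
  }
  f <- if (spec$tooth_amplitude > 0) {
    function(s) base(s) * (1 + spec$tooth_amplitude *
                             sin(2 * pi * spec$n_teeth * s +
                                   spec$tooth_phase))
  } else base
  lo <- min(f(seq(0, 1, length.out = 256)))
  if (lo <= 1e-9)
    stop("profile is not strictly positive on [0, 1]: min ma = ",
         signif(lo, 4))
  f
}

#' Parametric mandible realizing a target MA profile
#'
#' Inverse construction used to validate the lever pipeline: the pivot
#' (condyle) sits at the origin, the adductor attachment at unit
#' distance, and the gnathal edge is a fan of points built step by step
#' so that (i) consecutive points are equidistant — arc-length
#' resampling at `n_edge_points` lands exactly on them — and (ii) point
#' `i` lies at distance `1 / ma*(s_i)` from the pivot. With zero noise,
#' [ma_curve] of the result recovers the target profile up to
#' resampling error only.
#'
#' @param spec A [diet_profile]; its `noise_sd` is applied as isotropic
#'   Gaussian noise to every landmark after construction.
#' @param n_edge_points Number of edge landmarks (>= 4; default 100).
#' @param seed Optional integer seed (required when `noise_sd > 0` for
#'   reproducibility).
#' @return A [landmark_config] with roles set, side `"right"`.
#' @export
mandible_from_profile <- function(spec, n_edge_points = 100L,
                                  seed = NULL) {
  stopifnot(inherits(spec, "diet_profile"))
  n_edge_points <- as.integer(n_edge_points)
  if (n_edge_points < 4L) stop("n_edge_points must be >= 4")
  f <- target_ma_profile(spec)
  s <- seq(0, 1, length.out = n_edge_points)
  r <- 1 / f(s)  # outlever radii; inlever length is 1
  # uniform chord step: long enough to bridge the largest radius change,
  # scaled so the edge is a plausible fraction of the outlever radius
  h <- max(0.9 * mean(r) / (n_edge_points - 1),
           1.05 * max(abs(diff(r))))
  theta <- numeric(n_edge_points)
  theta[1] <- pi / 2
  for (i in seq_len(n_edge_points - 1L)) {
    cosd <- (r[i]^2 + r[i + 1]^2 - h^2) / (2 * r[i] * r[i + 1])
    theta[i + 1L] <- theta[i] + acos(min(1, max(-1, cosd)))
  }
  edge <- cbind(r * cos(theta), r * sin(theta))
  pts <- rbind(condyle = c(0, 0),
               adductor = c(0, -1),
               edge)
  rownames(pts) <- c("condyle", "adductor",
                     sprintf("edge_%03d", seq_len(n_edge_points)))
  if (spec$noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    pts <- pts + matrix(stats::rnorm(length(pts), sd = spec$noise_sd),
                        nrow(pts))
  }
  roles <- c(condyle = "condyle_anterior", adductor = "adductor_attachment",
             stats::setNames(rep("edge_point", n_edge_points),
                             rownames(pts)[-(1:2)]))
  cfg <- landmark_config(paste0("synthetic_", spec$diet_class), pts,
                         side = "right", roles = roles)
  attr(cfg, "diet_class") <- spec$diet_class
  cfg
}

#' Fragmented fossil replicates of a configuration
#'
#' Emulates several compression-fossil specimens of one individual:
#' each copy is the original under a random rigid motion (rotation +
#' translation), optional reflection (side relabelled accordingly), and
#' isotropic landmark noise representing taphonomic distortion.
#'
#' @param config A [landmark_config] (2D).
#' @param n_copies Number of replicates (>= 2).
#' @param distortion_sd Landmark noise standard deviation.
#' @param seed Integer seed.
#' @param reflect_prob Probability a copy is mirrored (default 0).
#' @return List of [landmark_config] objects,
#'   ids `<id>_frag1..n`.
#' @export
fragment_fossil <- function(config, n_copies = 4L, distortion_sd = 0.01,
                            seed = NULL, reflect_prob = 0) {
  stopifnot(inherits(config, "landmark_config"))
  n_copies <- as.integer(n_copies)
  if (n_copies < 2L) stop("n_copies must be >= 2")
  if (config_dim(config) != 2L)
    stop("fragment_fossil supports 2D (compression fossil) input")
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_copies), function(i) {
    pts <- config$points
    side <- if (is.na(config$side)) "right" else config$side
    if (stats::runif(1) < reflect_prob) {
      pts[, 1] <- -pts[, 1]
      side <- if (side == "right") "left" else "right"
    }
    ang <- stats::runif(1, 0, 2 * pi)
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
    pts <- pts %*% R
    pts <- sweep(pts, 2, stats::runif(2, -5, 5), `+`)
    if (distortion_sd > 0)
      pts <- pts + matrix(stats::rnorm(length(pts), sd = distortion_sd),
                          nrow(pts))
    landmark_config(paste0(config$specimen_id, "_frag", i), pts,
                    side = side, roles = config$roles)
  })
}

#' Simulate a pure-birth tree
#'
#' Yule (pure-birth) tree with unit speciation rate, conditioned on the
#' number of tips; tips labelled `T1..Tn`.
#'
#' @param n_tips Number of tips (>= 3).
#' @param seed Integer seed.
#' @return An [ape::phylo] tree with branch lengths.
#' @export
simulate_tree <- function(n_tips, seed = NULL) {
  n_tips <- as.integer(n_tips)
  if (n_tips < 3L) stop("n_tips must be >= 3")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  tree$tip.label <- paste0("T", seq_len(n_tips))
  tree
}

#' Simulate Brownian-motion traits on a tree
#'
#' Each trait is an independent multivariate-normal draw with
#' covariance `rate * C`, the Brownian expectation on the tree.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param n_traits Number of independent traits.
#' @param rate Brownian rate (> 0).
#' @param seed Integer seed.
#' @return A tips-by-traits matrix (rownames = tip labels).
#' @export
simulate_bm_traits <- function(tree, n_traits = 1L, rate = 1, seed = NULL) {
  if (rate <= 0) stop("rate must be positive")
  C <- phylo_covariance(tree)
  if (!is.null(seed)) set.seed(seed)
  Z <- MASS::mvrnorm(n_traits, mu = rep(0, nrow(C)), Sigma = rate * C)
  X <- if (n_traits == 1L) matrix(Z, ncol = 1) else t(Z)
  dimnames(X) <- list(rownames(C), paste0("trait", seq_len(n_traits)))
  X
}

#' Generate a complete synthetic comparative study
#'
#' End-to-end fixture mirroring a comparative mandible dataset: a
#' pure-birth species tree, diet classes assigned to contiguous blocks
#' of the tree's tip order (so diet carries phylogenetic signal),
#' per-species parametric mandibles whose profile parameters (level,
#' curvature) carry Brownian-motion jitter around the class defaults,
#' and one fossil built from an intermediate (omnivore) profile and
#' fragmented into noisy replicates, with its tip grafted onto the stem
#' of the tree.
#'
#' @param n_species Number of extant species (default 43, a typical
#'   polyneopteran sampling).
#' @param class_mix Named proportions over
#'   `herbivore`/`omnivore`/`carnivore`, summing to 1.
#' @param seed Integer seed driving every random draw.
#' @param n_edge_points Edge landmarks per mandible (default 200, a
#'   dense outline digitization).
#' @param noise_sd Landmark digitization noise per species (default
#'   0.002, i.e. well below the vertex spacing of the digitized edge).
#' @param tooth_amplitude Relative amplitude of the per-species dental
#'   relief (random phase and tooth count per species); the
#'   small-scale morphology that polynomial fits treat as residual
#'   noise.
#' @param jitter_sd Standard deviations of the Brownian jitter on
#'   `level` and `curvature` across the tree.
#' @param n_fossil_copies Number of fossil fragments (default 4).
#' @param fossil_distortion_sd Landmark noise of the fossil fragments.
#' @return An object of class `ma_study`: `configs` (named list of
#'   extant [landmark_config]s), `diet` (named character), `tree`
#'   (extant tips + fossil tip `CFMR`), `fossil_copies`,
#'   `fossil_true_config`, `profiles` (per-species parameter table),
#'   `fossil_id`, `seed`.
#' @export
make_study <- function(n_species = 43L,
                       class_mix = c(herbivore = 0.4, omnivore = 0.3,
                                     carnivore = 0.3),
                       seed = 1L,
                       n_edge_points = 200L,
                       noise_sd = 0.002,
                       tooth_amplitude = 0.015,
                       jitter_sd = c(level = 0.04, curvature = 0.10),
                       n_fossil_copies = 4L,
                       fossil_distortion_sd = 0.01) {
  n_species <- as.integer(n_species)
  if (abs(sum(class_mix) - 1) > 1e-8)
    stop("class_mix proportions must sum to 1")
  classes <- c("herbivore", "omnivore", "carnivore")
  if (!all(names(class_mix) %in% classes))
    stop("class_mix names must be among: ", paste(classes, collapse = ", "))
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 4L + n_species)

  tree <- simulate_tree(n_species, seed = sub_seeds[1])
  # contiguous blocks of the cladewise tip order ~ clade-level diet
  tip_order <- tree$tip.label[tree$edge[tree$edge[, 2] <=
                                          n_species, 2]]
  counts <- floor(class_mix[classes[classes %in% names(class_mix)]] *
                    n_species)
  counts[is.na(counts)] <- 0
  rem <- n_species - sum(counts)
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1
  diet <- stats::setNames(rep(names(counts), counts), tip_order)
  diet <- diet[tree$tip.label]

  jit <- simulate_bm_traits(tree, 2L, rate = 1, seed = sub_seeds[2])
  jit <- scale(jit)  # unit variance across tips, tree structure kept
  profiles <- data.frame(species = tree$tip.label, diet = diet,
                         level = NA_real_, curvature = NA_real_,
                         shape = NA_character_, stringsAsFactors = FALSE)
  configs <- vector("list", n_species)
  names(configs) <- tree$tip.label
  for (i in seq_len(n_species)) {
    base <- .diet_defaults[[diet[i]]]
    level <- max(0.12, base$level + jitter_sd[["level"]] * jit[i, 1])
    curv <- max(0.05, base$curvature + jitter_sd[["curvature"]] * jit[i, 2])
    if (base$shape == "linear") curv <- min(curv, 0.85)  # keep ma(1) > 0
    spec <- diet_profile(diet[i], level = level, shape = base$shape,
                         curvature = curv, noise_sd = noise_sd,
                         tooth_amplitude = tooth_amplitude,
                         n_teeth = sample(8:12, 1),
                         tooth_phase = stats::runif(1, 0, 2 * pi))
    cfg <- mandible_from_profile(spec, n_edge_points,
                                 seed = sub_seeds[4L + i])
    cfg$specimen_id <- tree$tip.label[i]
    configs[[i]] <- cfg
    profiles$level[i] <- level
    profiles$curvature[i] <- curv
    profiles$shape[i] <- base$shape
  }

  fossil_spec <- diet_profile("omnivore", noise_sd = 0,
                              tooth_amplitude = tooth_amplitude,
                              n_teeth = sample(8:12, 1),
                              tooth_phase = stats::runif(1, 0, 2 * pi))
  fossil_true <- mandible_from_profile(fossil_spec, n_edge_points)
  fossil_true$specimen_id <- "CFMR_true"
  fossil_copies <- fragment_fossil(fossil_true,
                                   n_copies = n_fossil_copies,
                                   distortion_sd = fossil_distortion_sd,
                                   seed = sub_seeds[3])
  tree_full <- add_fossil_tip(tree, "CFMR")

  structure(list(configs = configs, diet = diet, tree = tree_full,
                 extant_tree = tree, fossil_copies = fossil_copies,
                 fossil_true_config = fossil_true, profiles = profiles,
                 fossil_id = "CFMR", seed = seed),
            class = "ma_study")
}

#' @export
print.ma_study <- function(x, ...) {
  cat("ma_study:", length(x$configs), "extant species +",
      length(x$fossil_copies), "fossil fragments (composite tip '",
      x$fossil_id, "'); seed ", x$seed, "\n", sep = "")
  cat("  diet classes:",
      paste(names(table(x$diet)), table(x$diet), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' Write a study bundle to disk in the pipeline's input formats
#'
#' Emits TPS landmark files (extant + fossil fragments), a Newick tree,
#' and a CSV metadata table, i.e. exactly what the file-based pipeline
#' entry points read back.
#'
#' @param study An `ma_study` from [make_study].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "ma_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_landmarks_csv(unname(study$configs),
                      file.path(dir, "extant_landmarks.csv"))
  write_landmarks_csv(study$fossil_copies,
                      file.path(dir, "fossil_fragments.csv"))
  ape::write.tree(study$tree, file.path(dir, "tree.nwk"))
  utils::write.csv(data.frame(specimen_id = names(study$diet),
                              diet = unname(study$diet)),
                   file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(dir)
}
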