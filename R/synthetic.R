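## Synthetic visual-field generator: planted defect-pattern archetypes,
## Dirichlet mixing near the convex hull, subject/eye structure and a
## configurable negative:positive imbalance, so the whole pipeline is
## testable without any clinical data.

#' Specification of a synthetic visual-field cohort
#'
#' Defaults emulate a baseline ocular-hypertension cohort: 76-point
#' full-threshold fields (Humphrey 30-2 layout minus the blind-spot points),
#' two to three reliable baseline tests per subject, and roughly eight
#' negative subjects per positive subject.
#'
#' @param d Measurement dimensions (default 76).
#' @param n_subjects Number of subjects.
#' @param samples_per_subject Integer vector of admissible per-subject test
#'   counts (each subject's count is sampled uniformly from it).
#' @param k_true Planted archetype count (atom 1 is the normal field).
#' @param baseline Foveal normal sensitivity in dB (default 30).
#' @param hill_slope Physiological decline of normal sensitivity with
#'   eccentricity, dB per degree (default 0.15; the "hill of vision").
#' @param defect_depth Mean sensitivity reduction of defect atoms, dB.
#' @param noise_sigma Stochastic perturbation scale, dB. Each test receives
#'   i.i.d. Gaussian noise of this SD per location plus a global
#'   general-height offset (whole-field sensitivity shift from pupil size,
#'   media, attention) of SD `height_ratio * noise_sigma`. Setting 0 gives
#'   exactly reconstructable fields.
#' @param height_ratio General-height SD as a fraction of `noise_sigma`
#'   (default 0.5).
#' @param noise_heterogeneity SD of the log-normal per-subject noise
#'   multiplier (default 0, matching a reliability-filtered cohort): patients differ in test reliability, so the
#'   effective noise scale varies between subjects (multiplier
#'   `exp(rnorm(1, 0, noise_heterogeneity))` applied to both the location
#'   noise and the height offsets of that subject's tests).
#' @param imbalance Negative:positive subject ratio (P(positive) =
#'   1/(1+imbalance)).
#' @param signal_strength Focality contrast between the classes; 0 removes
#'   all class signal. Both classes share one distribution of *total*
#'   defect mass; a positive subject concentrates that mass on a single
#'   expressed defect pattern (drawn uniformly), whereas a negative
#'   subject spreads it diffusely. Disease therefore changes the *shape*
#'   of the mixing-weight distribution, not its mean: focal versus diffuse
#'   loss, the classic perimetric criterion.
#' @param defect_mass Beta concentration of the total defect mass shared
#'   by both classes: mass ~ Beta(defect_mass, alpha_normal).
#' @param alpha_normal Beta concentration of the normal atom in the total
#'   defect-mass draw (larger keeps cohorts more normal).
#' @param alpha_defect Dirichlet concentration of the defect-mass *split*
#'   for negative subjects (and for positives at `signal_strength = 0`).
#'   Values below one make even negatives focal and push samples near the
#'   hull vertices; the default 1.5 keeps negatives diffuse.
#' @param seed Integer seed.
#' @return Named list of class `"vf_spec"`.
#' @export
vf_spec <- function(d = 76L, n_subjects = 400L, samples_per_subject = 2:3,
                    k_true = 6L, baseline = 30, hill_slope = 0.15,
                    defect_depth = 20, noise_sigma = 4, height_ratio = 0.5,
                    noise_heterogeneity = 0, imbalance = 8,
                    signal_strength = 3.5, alpha_normal = 9,
                    alpha_defect = 1.5, defect_mass = 4, seed = 1L) {
  spec <- list(d = as.integer(d), n_subjects = as.integer(n_subjects),
               samples_per_subject = as.integer(samples_per_subject),
               k_true = as.integer(k_true), baseline = baseline,
               hill_slope = hill_slope, defect_depth = defect_depth,
               noise_sigma = noise_sigma, height_ratio = height_ratio,
               noise_heterogeneity = noise_heterogeneity,
               imbalance = imbalance,
               signal_strength = signal_strength,
               alpha_normal = alpha_normal, alpha_defect = alpha_defect,
               defect_mass = defect_mass,
               seed = as.integer(seed))
  if (spec$d < 2L) fail_input("d must be >= 2")
  if (spec$k_true < 2L) fail_input("k_true must be >= 2")
  if (spec$imbalance < 1) fail_input("imbalance must be >= 1")
  if (spec$noise_sigma < 0) fail_input("noise_sigma must be >= 0")
  if (any(spec$samples_per_subject < 1L)) {
    fail_input("samples_per_subject must be >= 1")
  }
  structure(spec, class = "vf_spec")
}

## Grid coordinates (degrees of visual angle) of the measurement locations.
## d = 76 uses the 30-2 row layout (4,6,8,10,10,10,10,8,6,4 points at 6-deg
## spacing); other d fall back to a near-square grid. The adjacency implied
## by these coordinates is an internal convention used to place contiguous
## defect blocks.
vf_grid_coords <- function(d) {
  if (d == 76L) {
    widths <- c(4L, 6L, 8L, 10L, 10L, 10L, 10L, 8L, 6L, 4L)
    ys <- seq(27, -27, by = -6)
  } else {
    ncol_ <- ceiling(sqrt(d))
    nrow_ <- ceiling(d / ncol_)
    widths <- rep(ncol_, nrow_)
    widths[nrow_] <- d - ncol_ * (nrow_ - 1L)
    ys <- seq_len(nrow_) * 6 - 3 * (nrow_ + 1)
    ys <- -ys
  }
  x <- unlist(lapply(widths, function(w) (seq_len(w) - (w + 1) / 2) * 6))
  y <- rep(ys, times = widths)
  cbind(x = x, y = y)
}

#' Planted visual-field archetypes
#'
#' Atom 1 is a normal field: `baseline` sensitivity at fixation declining
#' with eccentricity at `hill_slope` dB/degree. Atoms `2..k_true` subtract
#' `defect_depth` dB on a contiguous block of locations confined to one
#' hemifield (defects respect the horizontal midline, as glaucomatous
#' arcuate and nasal-step losses do). Entries are clipped at zero with a
#' warning if the defect exceeds the local normal sensitivity. Deterministic
#' given `spec$seed`.
#'
#' @param spec A [vf_spec()].
#' @return d x k_true matrix of archetype fields.
#' @export
make_archetypes <- function(spec) {
  if (!inherits(spec, "vf_spec")) fail_input("spec must be a vf_spec")
  set.seed(spec$seed)
  d <- spec$d; k <- spec$k_true
  coords <- vf_grid_coords(d)
  ecc <- sqrt(rowSums(coords^2))
  normal <- spec$baseline - spec$hill_slope * ecc
  atoms <- matrix(normal, d, k)
  block_size <- max(4L, round(d / 6))
  block_for <- function(ctr) {
    hemi <- if (coords[ctr, "y"] >= 0) coords[, "y"] >= 0 else coords[, "y"] < 0
    dd <- sqrt((coords[, "x"] - coords[ctr, "x"])^2 +
                 (coords[, "y"] - coords[ctr, "y"])^2)
    dd[!hemi] <- Inf
    sort(order(dd)[seq_len(min(block_size, sum(hemi)))])
  }
  used <- list()
  for (j in 2L:k) {
    # resample the centre until the block differs from all earlier ones
    for (try in 1:50) {
      block <- block_for(sample.int(d, 1L))
      if (!any(vapply(used, identical, logical(1), y = block))) break
    }
    used[[length(used) + 1L]] <- block
    atoms[block, j] <- atoms[block, j] - spec$defect_depth
  }
  if (any(atoms < 0)) {
    warning("defect depth exceeds local normal sensitivity; clipping at 0 dB",
            call. = FALSE)
    atoms <- pmax(atoms, 0)
  }
  atoms
}

## Dirichlet draw via normalised gamma variates.
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(g) <= 0) { g <- rep(0, length(alpha)); g[which.max(alpha)] <- 1 }
  g / sum(g)
}

#' Sample a synthetic cohort
#'
#' Subjects are labelled positive with probability `1/(1+imbalance)`. Each
#' subject draws one mixing-weight vector over the planted archetypes (the
#' defect mix is a property of the eye, shared by its repeat tests),
#' hierarchically: a total defect mass `M ~ Beta(defect_mass,
#' alpha_normal)` with the *same* distribution in both classes, split
#' across the defect atoms by a Dirichlet draw — diffuse
#' (`alpha_defect` each) for negatives, concentrated on one uniformly
#' chosen expressed pattern for positives (that atom's concentration is
#' raised by `2 * signal_strength`, the others shrunk by
#' `1 + signal_strength`). Class membership therefore changes the
#' focality of loss, not its expected amount. Each of the subject's tests
#' is the convex combination of archetypes plus a global general-height
#' offset and i.i.d. Gaussian noise, clipped at 0 dB.
#'
#' @param spec A [vf_spec()].
#' @return An object of class `"synthetic_vf"`: list with `cohort` (a
#'   [vf_cohort()]), `true_archetypes` (d x k_true), `true_weights`
#'   (k_true x m, one simplex column per sample) and `spec`.
#' @export
sample_cohort <- function(spec) {
  if (!inherits(spec, "vf_spec")) fail_input("spec must be a vf_spec")
  atoms <- make_archetypes(spec)
  set.seed(derive_seed(spec$seed, 1L))
  k <- spec$k_true
  p_pos <- 1 / (1 + spec$imbalance)
  labels_subj <- stats::rbinom(spec$n_subjects, 1L, p_pos)

  feats <- list(); wts <- list()
  subject_ids <- character(0); eye_ids <- character(0); labels <- integer(0)
  for (s in seq_len(spec$n_subjects)) {
    M <- stats::rbeta(1L, spec$defect_mass, spec$alpha_normal)
    zalpha <- rep(spec$alpha_defect, k - 1L)
    if (labels_subj[s] == 1L) {
      expressed <- sample.int(k - 1L, 1L)
      zalpha <- zalpha / (1 + spec$signal_strength)
      zalpha[expressed] <- spec$alpha_defect + 2 * spec$signal_strength
    }
    z <- rdirichlet1(zalpha)
    w <- c(1 - M, M * z)
    n_i <- if (length(spec$samples_per_subject) == 1L) {
      spec$samples_per_subject
    } else {
      sample(spec$samples_per_subject, 1L)
    }
    base_field <- drop(atoms %*% w)
    sigma_s <- spec$noise_sigma *
      exp(stats::rnorm(1, 0, spec$noise_heterogeneity))
    for (r in seq_len(n_i)) {
      x <- base_field
      if (spec$noise_sigma > 0) {
        height <- stats::rnorm(1, 0, spec$height_ratio * sigma_s)
        x <- pmax(x + height + stats::rnorm(spec$d, 0, sigma_s), 0)
      }
      feats[[length(feats) + 1L]] <- x
      wts[[length(wts) + 1L]] <- w
      subject_ids <- c(subject_ids, sprintf("S%04d", s))
      eye_ids <- c(eye_ids, sprintf("S%04d_E%d", s, r))
      labels <- c(labels, labels_subj[s])
    }
  }
  features <- do.call(cbind, feats)
  true_weights <- do.call(cbind, wts)
  structure(list(
    cohort = vf_cohort(features, labels, subject_ids, eye_ids),
    true_archetypes = atoms,
    true_weights = true_weights,
    spec = spec
  ), class = "synthetic_vf")
}

#' @export
print.synthetic_vf <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d samples from %d subjects (%d positive), d = %d, k_true = %d\n",
              ncol(x$cohort$features), x$spec$n_subjects,
              sum(x$cohort$labels[!duplicated(x$cohort$subject_ids)]),
              x$spec$d, x$spec$k_true))
  invisible(x)
}

#' Match recovered atoms to planted archetypes
#'
#' Greedy maximum-|correlation| assignment between the columns of two atom
#' matrices; returns the matched absolute Pearson correlations.
#'
#' @param recovered,truth d x k matrices.
#' @return Numeric vector of length `ncol(truth)` of matched |correlations|.
#' @export
match_archetypes <- function(recovered, truth) {
  C <- abs(stats::cor(recovered, truth))
  k <- ncol(truth)
  out <- numeric(k)
  for (i in seq_len(k)) {
    best <- which(C == max(C, na.rm = TRUE), arr.ind = TRUE)[1L, ]
    out[best[["col"]]] <- C[best[["row"]], best[["col"]]]
    C[best[["row"]], ] <- -Inf
    C[, best[["col"]]] <- -Inf
  }
  out
}
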