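# Score features, the composite score, Platt-scaled probabilities,
# calibration fitting and quality metrics, and F1/F-beta threshold selection.

#' Optimised score weights for the four site classes
#'
#' The composite score is `s = b1*dRMSD + b2*TRMSD + b3*HisAnglesScore + c`,
#' with separate weights for His-containing vs His-free sites and for
#' 3-residue vs 4-plus-residue sites (b3 = 0 when there is no histidine).
#'
#' @return Named list of four parameter sets
#'   (`his_4plus`, `his_3`, `nohis_4plus`, `nohis_3`), each with
#'   `b1`, `b2`, `b3`, `c`.
#' @export
score_parameters <- function() {
  list(
    his_4plus   = list(b1 = 12.3, b2 = 5.0,  b3 = 0.3, c = 0),
    his_3       = list(b1 = 13.8, b2 = 0.7,  b3 = 0.2, c = 8.1),
    nohis_4plus = list(b1 = 13.8, b2 = 14.5, b3 = 0,   c = 5.5),
    nohis_3     = list(b1 = 12.9, b2 = 1.6,  b3 = 0,   c = 14.4)
  )
}

#' Which score-parameter case applies to a site
#'
#' @param has_his Does the site contain at least one histidine?
#' @param n_residues Number of binding residues in the site.
#' @return One of `"his_4plus"`, `"his_3"`, `"nohis_4plus"`, `"nohis_3"`.
#' @export
score_case <- function(has_his, n_residues) {
  paste0(if (has_his) "his" else "nohis",
         if (n_residues >= 4L) "_4plus" else "_3")
}

#' Root-mean-square deviation of coordination distances from ideal
#'
#' @param distances Observed ion-ligand distances (Angstrom).
#' @param ideals Per-ligand ideal distances (Angstrom).
#' @return dRMSD in Angstrom.
#' @export
drmsd <- function(distances, ideals) {
  if (length(distances) != length(ideals)) {
    stop("distances and ideals differ in length")
  }
  sqrt(mean((distances - ideals)^2))
}

#' Histidine imidazole angle score
#'
#' RMS of the alpha ("angle to plane") deviations plus RMS of the beta
#' ("angle to m->N") deviations from their ideal values (0 by default).
#'
#' @param alphas,betas Per-histidine angles in degrees.
#' @param alpha_ideal,beta_ideal Ideal angle values (degrees).
#' @return Score in degrees (lower is better).
#' @export
his_angles_score <- function(alphas, betas, alpha_ideal = 0, beta_ideal = 0) {
  if (length(alphas) == 0L || length(alphas) != length(betas)) {
    stop("his_angles_score needs equally many non-empty alpha and beta values")
  }
  sqrt(mean((alphas - alpha_ideal)^2)) + sqrt(mean((betas - beta_ideal)^2))
}

#' Composite raw score of a candidate site
#'
#' @param drmsd_value dRMSD feature (Angstrom).
#' @param trmsd_value Template superposition RMSD (Angstrom).
#' @param his_score Imidazole angle score (degrees); ignored (weight 0) for
#'   His-free cases and may be NA there.
#' @param case Score case (see [score_case()]).
#' @param params Parameter table, defaulting to [score_parameters()].
#' @return Raw score `s` (lower is better).
#' @export
composite_score <- function(drmsd_value, trmsd_value, his_score, case,
                            params = score_parameters()) {
  p <- params[[case]]
  if (is.null(p)) stop("unknown score case: ", case)
  hs <- if (p$b3 == 0) 0 else his_score
  if (p$b3 != 0 && (is.na(hs) || is.null(hs))) {
    stop("his-containing case requires a histidine angle score")
  }
  p$b1 * drmsd_value + p$b2 * trmsd_value + p$b3 * hs + p$c
}

#' Two-parameter logistic (Platt) probability model
#'
#' @param A Slope (negative: lower scores map to higher probabilities).
#' @param B Intercept.
#' @return `CalibrationModel` list.
#' @export
calibration_model <- function(A, B) {
  structure(list(A = A, B = B), class = "CalibrationModel")
}

#' Fit the logistic exactly through two (score, probability) anchor points
#'
#' Solves `logit(p) = A*s + B` through two anchors in closed form.
#'
#' @param s1,p1,s2,p2 The two anchor pairs.
#' @return `CalibrationModel`.
#' @export
platt_from_anchors <- function(s1, p1, s2, p2) {
  logit <- function(p) log(p / (1 - p))
  A <- (logit(p2) - logit(p1)) / (s2 - s1)
  B <- logit(p1) - A * s1
  calibration_model(A, B)
}

#' Default shipped calibration model
#'
#' Derived by exact two-point interpolation through the published anchor
#' pairs (s = 3.36, p = 0.996) and (s = 15.32, p = 0.30); approximately
#' A = -0.5322, B = 7.3055.
#'
#' @return `CalibrationModel`.
#' @export
default_calibration <- function() {
  platt_from_anchors(3.36, 0.996, 15.32, 0.30)
}

#' Convert a raw score into a calibrated probability
#'
#' `p = 1 / (1 + exp(-(A*s + B)))`.
#'
#' @param s Raw score(s).
#' @param model `CalibrationModel`.
#' @return Probability in [0, 1], vectorised over `s`.
#' @export
platt_probability <- function(s, model = default_calibration()) {
  1 / (1 + exp(-(model$A * s + model$B)))
}

#' Fit Platt scaling by maximum likelihood
#'
#' Minimises the negative log-likelihood of labels under the logistic model
#' on a random 80% training split; the held-out 20% is returned for
#' calibration-quality metrics.
#'
#' @param scores Raw scores.
#' @param labels 0/1 labels (1 = true site).
#' @param split_seed Seed for the train/validation split.
#' @param train_fraction Fraction used for fitting.
#' @return List: `model` (`CalibrationModel`), `validation`
#'   (data frame of held-out scores/labels), `nll` (training NLL).
#' @export
fit_platt <- function(scores, labels, split_seed = 1L,
                      train_fraction = 0.8) {
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) < 2L) {
    stop("degenerate fit: both classes must be present")
  }
  n <- length(scores)
  idx <- withr_seed(split_seed, sample.int(n, size = floor(train_fraction * n)))
  s_tr <- scores[idx]; y_tr <- labels[idx]
  nll <- function(par) {
    p <- 1 / (1 + exp(-(par[1] * s_tr + par[2])))
    p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
    -sum(y_tr * log(p) + (1 - y_tr) * log(1 - p))
  }
  # bounded to guard the perfectly separated pathology, where |A| diverges
  if (max(s_tr[y_tr == 1]) < min(s_tr[y_tr == 0]) ||
      min(s_tr[y_tr == 1]) > max(s_tr[y_tr == 0])) {
    warning("training scores are perfectly separated; ",
            "slope bounded by optimizer bounds")
  }
  fit <- stats::optim(c(-0.1, 0), nll, method = "L-BFGS-B",
                      lower = c(-50, -200), upper = c(50, 200))
  list(model = calibration_model(fit$par[1], fit$par[2]),
       validation = data.frame(score = scores[-idx], label = labels[-idx]),
       nll = fit$value)
}

# run expr under a local RNG seed without touching the global stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Brier score of probabilistic predictions
#'
#' Mean squared difference between predicted probabilities and 0/1 outcomes.
#'
#' @param probs Predicted probabilities.
#' @param labels Observed 0/1 outcomes.
#' @return Brier score in [0, 1].
#' @export
brier_score <- function(probs, labels) {
  if (length(probs) == 0L || length(probs) != length(labels)) {
    stop("probs and labels must be non-empty and aligned")
  }
  mean((probs - labels)^2)
}

#' Logarithmic loss of probabilistic predictions
#'
#' @param probs Predicted probabilities (clipped to `[clip, 1 - clip]`).
#' @param labels Observed 0/1 outcomes.
#' @param clip Clipping bound.
#' @return Mean negative log-likelihood.
#' @export
log_loss <- function(probs, labels, clip = 1e-15) {
  if (length(probs) == 0L || length(probs) != length(labels)) {
    stop("probs and labels must be non-empty and aligned")
  }
  f <- pmin(pmax(probs, clip), 1 - clip)
  -mean(labels * log(f) + (1 - labels) * log(1 - f))
}

#' F1- and F-beta-optimal probability thresholds from a PR curve
#'
#' @param pr_points Data frame with columns `threshold`, `precision`,
#'   `recall`.
#' @param beta Beta for the F-beta score (default 2, recall-weighted).
#' @return List with `best_f1`/`best_fbeta`, each carrying `value` and the
#'   `thresholds` achieving it.
#' @export
select_thresholds <- function(pr_points, beta = 2) {
  P <- pr_points$precision
  R <- pr_points$recall
  f1 <- ifelse(P + R == 0, 0, 2 * P * R / (P + R))
  fb <- ifelse(beta^2 * P + R == 0, 0,
               (1 + beta^2) * P * R / (beta^2 * P + R))
  list(
    best_f1 = list(value = max(f1),
                   thresholds = pr_points$threshold[f1 == max(f1)]),
    best_fbeta = list(value = max(fb), beta = beta,
                      thresholds = pr_points$threshold[fb == max(fb)])
  )
}
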