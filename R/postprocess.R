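# End-to-end pipeline: candidate search -> placement -> rotamer sampling ->
# scoring -> probability -> compression -> thresholding, plus CSV and PyMOL
# script writers.

#' Pipeline configuration
#'
#' @param include_rotamers Sample His chi2 rotamers (default TRUE).
#' @param min_probability Reporting threshold on the calibrated probability.
#' @param compression_radius Suppression radius between kept predictions
#'   (Angstrom); chosen because almost all binuclear zinc pairs are further
#'   apart than 2.6 Angstrom.
#' @param pair_cutoff Candidate pair cutoff (Angstrom, strict).
#' @param both_sides Emit both mirror placements of His-free 3-residue
#'   sites instead of deterministic side A.
#' @param initial_offset Off-plane offset of the 3-residue starting points.
#' @param max_assemblies Combinatorial guard for site assembly.
#' @param seed RNG seed recorded in outputs.
#' @return `PipelineConfig` list.
#' @export
pipeline_config <- function(include_rotamers = TRUE, min_probability = 0.15,
                            compression_radius = 2.6, pair_cutoff = 7.0,
                            both_sides = FALSE, initial_offset = 1.5,
                            max_assemblies = 10000L, seed = 1L) {
  stopifnot(compression_radius > 0, pair_cutoff > 0,
            min_probability >= 0, min_probability <= 1)
  list(include_rotamers = include_rotamers,
       min_probability = min_probability,
       compression_radius = compression_radius,
       pair_cutoff = pair_cutoff, both_sides = both_sides,
       initial_offset = initial_offset,
       max_assemblies = as.integer(max_assemblies), seed = as.integer(seed))
}

# Score one candidate site; returns a list of prediction records (one, or
# two under both_sides for His-free 3-residue sites).
.score_candidate_site <- function(site, index, config, calibration) {
  residues <- site$residues
  tpl <- index$templates[[site$template_id]]
  bps <- lapply(residues, `[[`, "bp")
  starts <- tryCatch(
    initial_zinc_estimate(bps, offset = config$initial_offset),
    error = function(e) { warning(conditionMessage(e)); NULL })
  if (is.null(starts)) return(list())
  has_his <- any(vapply(residues, function(r) r$res_type == "HIS", TRUE))

  refine_from <- function(start) {
    chosen <- select_binding_atoms(residues, start)
    refine_zinc_position(chosen, start)
  }
  placements <- lapply(starts, refine_from)

  emit <- list()
  pick <- function(placement, residues_now) {
    chosen <- placement$chosen_atoms
    angles <- .site_his_angles(residues_now, chosen, placement$zinc_coord)
    his_score <- if (length(angles))
      his_angles_score(vapply(angles, `[[`, 0, "alpha"),
                       vapply(angles, `[[`, 0, "beta")) else NA_real_
    if (config$include_rotamers && has_his) {
      rs <- sample_his_rotamers(residues_now, placement)
      placement <- rs$placement
      placement$side <- "n/a"
      residues_now <- rs$residues
      his_score <- rs$score
      angles <- rs$angles
    }
    n_res <- length(residues_now)
    case <- score_case(has_his, n_res)
    t_coords <- do.call(rbind, lapply(tpl$residues, `[[`, "coord"))
    t_types <- vapply(tpl$residues, `[[`, "", "res_type")
    q_coords <- do.call(rbind, lapply(placement$chosen_atoms, `[[`, "coord"))
    q_types <- vapply(placement$chosen_atoms, `[[`, "", "res_type")
    trmsd <- superimpose_rmsd(q_coords, t_coords, q_types, t_types)
    s <- composite_score(placement$drmsd, trmsd, his_score, case)
    p <- platt_probability(s, calibration)
    list(site = site, placement = placement,
         score = list(drmsd = placement$drmsd, trmsd = trmsd,
                      his_angles_score = his_score, s = s, p = p,
                      case = case, template_id = site$template_id))
  }

  if (length(placements) == 1L) {
    emit[[1]] <- pick(placements[[1]], residues)
  } else {
    if (has_his) {
      scores <- vapply(placements, function(pl) {
        ang <- .site_his_angles(residues, pl$chosen_atoms, pl$zinc_coord)
        his_angles_score(vapply(ang, `[[`, 0, "alpha"),
                         vapply(ang, `[[`, 0, "beta"))
      }, 0)
      pl <- choose_three_residue_side(placements, scores)
      emit[[1]] <- pick(pl, residues)
    } else if (config$both_sides) {
      for (k in 1:2) {
        pl <- placements[[k]]; pl$side <- c("A", "B")[k]
        emit[[length(emit) + 1L]] <- pick(pl, residues)
      }
    } else {
      pl <- choose_three_residue_side(placements)
      emit[[1]] <- pick(pl, residues)
    }
  }
  emit
}

#' Compress overlapping predictions
#'
#' Iterative best-first suppression: keep the lowest-score (best) remaining
#' prediction, discard every other prediction within `radius` of it, repeat.
#' Score ties break on the (chain, seq_id) of the first site residue, then
#' on the template id, so the result is order-independent.
#'
#' @param predictions List of prediction records (`$placement$zinc_coord`,
#'   `$score$s`).
#' @param radius Suppression radius (Angstrom).
#' @return The retained predictions, ranked (field `rank` added).
#' @export
compress_predictions <- function(predictions, radius = 2.6) {
  if (length(predictions) <= 1L) {
    if (length(predictions) == 1L) predictions[[1]]$rank <- 1L
    return(predictions)
  }
  s <- vapply(predictions, function(p) p$score$s, 0)
  tie1 <- vapply(predictions, function(p) {
    r <- p$site$residues[[1]]
    sprintf("%s:%09d", r$chain, r$seq_id)
  }, "")
  tie2 <- vapply(predictions, function(p) p$site$template_id, "")
  ord <- order(s, tie1, tie2)
  coords <- do.call(rbind, lapply(predictions,
                                  function(p) p$placement$zinc_coord))
  kept <- integer()
  alive <- rep(TRUE, length(predictions))
  for (i in ord) {
    if (!alive[i]) next
    kept <- c(kept, i)
    d <- sqrt(colSums((t(coords) - coords[i, ])^2))
    alive[d <= radius] <- FALSE
  }
  out <- predictions[kept]
  for (k in seq_along(out)) out[[k]]$rank <- k
  out
}

#' Run the full prediction pipeline over one or more structures
#'
#' Per structure: extract binding residues, collect pairs under the cutoff,
#' query the inverted index, assemble candidate sites, place and score the
#' ion for each (with optional His rotamer sampling), convert scores to
#' probabilities, compress within the suppression radius, and apply the
#' probability threshold.  Per-structure failures are isolated: the batch
#' continues and the failure is recorded in the summary.
#'
#' @param structures A `ProteinStructure`, a list of them, or a character
#'   vector of file paths.
#' @param index `InvertedIndex` (see [build_inverted_index()]); or a
#'   `TemplateLibrary`, which is indexed with defaults.
#' @param config `PipelineConfig`.
#' @param calibration `CalibrationModel`; defaults to the model stored with
#'   the library, else the shipped anchors.
#' @return List: `predictions` (flat list over structures, compressed and
#'   thresholded), `summary` (per-structure data frame: structure_id,
#'   n_residues, n_pairs, n_candidates, n_predictions, status, elapsed).
#' @export
run_pipeline <- function(structures, index, config = pipeline_config(),
                         calibration = NULL) {
  if (inherits(structures, "ProteinStructure")) {
    structures <- list(structures)
  } else if (is.character(structures)) {
    structures <- as.list(structures)
  }
  if (is.null(index$postings)) index <- build_inverted_index(index)
  if (is.null(calibration)) {
    calibration <- if (!is.null(index$calibration$A))
      calibration_model(index$calibration$A, index$calibration$B)
    else default_calibration()
  }
  all_pred <- list()
  summary_rows <- list()
  for (src in structures) {
    t0 <- proc.time()[["elapsed"]]
    rec <- tryCatch({
      st <- if (inherits(src, "ProteinStructure")) src else
        parse_structure(src)
      cand <- collect_candidate_pairs(st, cutoff = config$pair_cutoff)
      hits <- query_index(cand, index)
      sites <- assemble_candidate_sites(hits, cand, index,
                                        config$max_assemblies)
      preds <- list()
      for (site in sites) {
        preds <- c(preds,
                   .score_candidate_site(site, index, config, calibration))
      }
      for (k in seq_along(preds)) preds[[k]]$structure_id <- st$structure_id
      preds <- compress_predictions(preds, config$compression_radius)
      preds <- Filter(function(p) p$score$p >= config$min_probability, preds)
      list(preds = preds,
           row = data.frame(
             structure_id = st$structure_id,
             n_residues = length(structure_residues(st)),
             n_pairs = nrow(cand$pairs), n_candidates = length(sites),
             n_predictions = length(preds), status = "ok",
             elapsed = proc.time()[["elapsed"]] - t0,
             stringsAsFactors = FALSE))
    }, error = function(e) {
      sid <- if (inherits(src, "ProteinStructure")) src$structure_id else
        as.character(src)
      list(preds = list(),
           row = data.frame(structure_id = sid, n_residues = NA_integer_,
                            n_pairs = NA_integer_, n_candidates = NA_integer_,
                            n_predictions = 0L,
                            status = paste("error:", conditionMessage(e)),
                            elapsed = proc.time()[["elapsed"]] - t0,
                            stringsAsFactors = FALSE))
    })
    all_pred <- c(all_pred, rec$preds)
    summary_rows[[length(summary_rows) + 1L]] <- rec$row
  }
  list(predictions = all_pred, summary = do.call(rbind, summary_rows))
}

#' Predictions as a data frame
#'
#' @param predictions Prediction list from [run_pipeline()].
#' @return Data frame with one row per prediction.
#' @export
predictions_table <- function(predictions) {
  if (length(predictions) == 0L) {
    return(data.frame(structure_id = character(), site_rank = integer(),
                      zinc_x = double(), zinc_y = double(), zinc_z = double(),
                      residues = character(), chosen_atoms = character(),
                      template_id = character(), drmsd = double(),
                      trmsd = double(), his_angles_score = double(),
                      s = double(), p = double(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(predictions, function(pr) {
    res_str <- paste(vapply(pr$site$residues, function(r)
      sprintf("%s:%s:%d", r$chain, r$res_type, r$seq_id), ""),
      collapse = ";")
    atom_str <- paste(vapply(pr$placement$chosen_atoms, `[[`, "", "atom"),
                      collapse = ";")
    z <- pr$placement$zinc_coord
    data.frame(structure_id = pr$structure_id,
               site_rank = if (is.null(pr$rank)) NA_integer_ else pr$rank,
               zinc_x = z[1], zinc_y = z[2], zinc_z = z[3],
               residues = res_str, chosen_atoms = atom_str,
               template_id = pr$score$template_id,
               drmsd = pr$score$drmsd, trmsd = pr$score$trmsd,
               his_angles_score = pr$score$his_angles_score,
               s = pr$score$s, p = pr$score$p, stringsAsFactors = FALSE)
  }))
}

#' Write predictions as CSV
#'
#' Coordinates are written with 4 decimals, scores with 3 (probabilities
#' keep 4); RFC-4180 quoting via [utils::write.csv()].
#'
#' @param predictions Prediction list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions_csv <- function(predictions, path) {
  df <- predictions_table(predictions)
  for (cl in c("zinc_x", "zinc_y", "zinc_z")) df[[cl]] <- round(df[[cl]], 4)
  for (cl in c("drmsd", "trmsd", "his_angles_score", "s")) {
    df[[cl]] <- round(df[[cl]], 3)
  }
  df$p <- round(df$p, 4)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Colour for a prediction probability
#'
#' Linear red -> yellow -> green ramp: red at p <= 0.15, yellow at p = 0.5,
#' green at p >= 0.85.
#'
#' @param p Probability (vectorised).
#' @return 3-column matrix of RGB values in [0, 1].
#' @export
probability_colour <- function(p) {
  t(vapply(p, function(pp) {
    if (pp <= 0.15) return(c(1, 0, 0))
    if (pp >= 0.85) return(c(0, 1, 0))
    if (pp <= 0.5) {
      f <- (pp - 0.15) / 0.35          # red -> yellow
      c(1, f, 0)
    } else {
      f <- (pp - 0.5) / 0.35           # yellow -> green
      c(1 - f, 1, 0)
    }
  }, c(0, 0, 0)))
}

#' Write a PyMOL command script visualising the predictions
#'
#' Plain-text `.pml` command file: loads the structure, adds one pseudoatom
#' sphere per predicted ion coloured by the probability ramp, and creates a
#' selection of the binding residues of each site.
#'
#' @param structure_path Path of the structure file to load.
#' @param predictions Prediction list.
#' @param path Output `.pml` path.
#' @return `path`, invisibly.
#' @export
write_pymol_script <- function(structure_path, predictions, path) {
  lines <- c(sprintf("load %s, query", structure_path),
             "hide everything, query", "show cartoon, query")
  for (k in seq_along(predictions)) {
    pr <- predictions[[k]]
    z <- pr$placement$zinc_coord
    rgb <- probability_colour(pr$score$p)[1, ]
    obj <- sprintf("zn_pred_%02d", k)
    lines <- c(lines,
      sprintf("pseudoatom %s, pos=[%.4f, %.4f, %.4f], vdw=0.8", obj,
              z[1], z[2], z[3]),
      sprintf("set_color col_%02d, [%.3f, %.3f, %.3f]", k,
              rgb[1], rgb[2], rgb[3]),
      sprintf("color col_%02d, %s", k, obj),
      sprintf("show spheres, %s", obj),
      sprintf("select site_%02d, query and (%s)", k,
              paste(vapply(pr$site$residues, function(r)
                sprintf("(chain %s and resi %d)", r$chain, r$seq_id), ""),
                collapse = " or ")),
      sprintf("show sticks, site_%02d", k))
  }
  lines <- c(lines, "deselect", "zoom query")
  writeLines(lines, path)
  invisible(path)
}
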