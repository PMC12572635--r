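# Template curation from zinc-bound structures, library serialization, and
# the inverted index over residue-pair types and Calpha/Cbeta distances.

LIBRARY_FORMAT_VERSION <- 1L

#' Extract observed zinc sites from a structure
#'
#' One site per zinc heteroatom: the coordinating set is the zinc-binding
#' residues (per [binding_atom_dictionary()]) with at least one listed atom
#' within `coordination_cutoff` of the ion; each residue contributes its
#' nearest listed atom once.
#'
#' @param structure A `ProteinStructure`.
#' @param coordination_cutoff Maximum ion-atom distance (Angstrom).  The
#'   default 2.8 brackets the 1.9-2.3 Angstrom coordination-bond range with
#'   margin for coordinate error.
#' @param element Het-ion element to extract sites for (default `"ZN"`).
#' @return List of `ObservedZincSite`s: `zinc_coord`, `zinc_occupancy`,
#'   `residues` (binding-residue objects), `chosen` (per-residue nearest
#'   listed atom: name, coord), `source_id`.
#' @export
extract_observed_sites <- function(structure, coordination_cutoff = 2.8,
                                   element = "ZN") {
  stopifnot(coordination_cutoff > 0)
  het <- structure$het_ions
  het <- het[het$element == element, , drop = FALSE]
  if (nrow(het) == 0L) return(list())
  bres <- extract_binding_residues(structure)
  dict <- binding_atom_dictionary()
  sites <- list()
  for (i in seq_len(nrow(het))) {
    zn <- c(het$x[i], het$y[i], het$z[i])
    keep <- list(); chosen <- list()
    for (r in bres) {
      cand <- dict[[r$res_type]]
      coords <- lapply(cand, .atom_coord, residue = r)
      ok <- !vapply(coords, is.null, TRUE)
      cand <- cand[ok]; coords <- coords[ok]
      d <- vapply(coords, function(p) .vnorm(p - zn), 0)
      j <- which.min(d)
      if (length(j) == 1L && d[j] <= coordination_cutoff) {
        keep[[length(keep) + 1L]] <- r
        chosen[[length(chosen) + 1L]] <-
          list(res_type = r$res_type, atom = cand[j], coord = coords[[j]],
               d_ideal = ideal_distance(r$res_type, cand[j]))
      }
    }
    sites[[length(sites) + 1L]] <- list(
      zinc_coord = zn, zinc_occupancy = het$occ[i],
      residues = keep, chosen = chosen,
      source_id = structure$structure_id)
  }
  sites
}

.site_combination <- function(site) {
  sort(vapply(site$residues, `[[`, "", "res_type"))
}

.site_to_template <- function(site, template_id) {
  ord <- order(vapply(site$residues, `[[`, "", "res_type"),
               vapply(site$residues, `[[`, "", "key"))
  res <- lapply(ord, function(i) {
    r <- site$residues[[i]]
    ch <- site$chosen[[i]]
    list(res_type = r$res_type, atom = ch$atom,
         coord = as.numeric(ch$coord),
         ca = if (is.null(r$ca)) NULL else as.numeric(r$ca),
         cb = if (is.null(r$cb)) NULL else as.numeric(r$cb),
         bp = as.numeric(r$bp))
  })
  list(template_id = template_id,
       combination = .site_combination(site),
       residues = res,
       zinc_coord = as.numeric(site$zinc_coord),
       source_id = site$source_id)
}

#' Curate templates from observed zinc sites
#'
#' Applies the three curation filters: at least `min_residues` coordinating
#' residues, ion occupancy strictly above `min_occupancy`, and the residue
#' combination seen in at least `min_sites` surviving sites spanning at
#' least `min_structures` distinct source structures.  One representative
#' site per accepted combination is picked uniformly at random under `seed`.
#'
#' @param sites List of observed sites (see [extract_observed_sites()]).
#' @param min_residues,min_sites,min_structures,min_occupancy Filter
#'   thresholds.
#' @param seed RNG seed for representative selection.
#' @return `TemplateLibrary`: list with `templates`, `curation_log`
#'   (per-combination counts and decision), `seed`, `version`,
#'   `calibration` (A/B of the shipped probability model).
#' @export
curate_templates <- function(sites, min_residues = 3L, min_sites = 3L,
                             min_structures = 3L, min_occupancy = 0.5,
                             seed = 1L) {
  surviving <- Filter(function(s) {
    length(s$residues) >= min_residues && s$zinc_occupancy > min_occupancy
  }, sites)
  combos <- vapply(surviving, function(s)
    paste(.site_combination(s), collapse = ","), "")
  log_rows <- list(); templates <- list()
  if (length(surviving) > 0L) {
    # canonical order so curation is invariant under input order
    for (cmb in sort(unique(combos))) {
      idx <- which(combos == cmb)
      srcs <- unique(vapply(surviving[idx], `[[`, "", "source_id"))
      accept <- length(idx) >= min_sites && length(srcs) >= min_structures
      reason <- if (accept) "accepted" else if (length(idx) < min_sites)
        sprintf("rejected: %d site(s) < %d", length(idx), min_sites) else
        sprintf("rejected: %d structure(s) < %d", length(srcs), min_structures)
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        combination = cmb, n_sites = length(idx), n_structures = length(srcs),
        decision = reason, stringsAsFactors = FALSE)
      if (accept) {
        # deterministic per-combination representative draw
        pick <- withr_seed(seed + length(templates),
                           idx[sample.int(length(idx), 1L)])
        tid <- sprintf("T%03d_%s", length(templates) + 1L,
                       gsub(",", "-", cmb))
        templates[[length(templates) + 1L]] <-
          .site_to_template(surviving[[pick]], tid)
      }
    }
  }
  cal <- default_calibration()
  list(templates = templates,
       curation_log = if (length(log_rows)) do.call(rbind, log_rows) else
         data.frame(combination = character(), n_sites = integer(),
                    n_structures = integer(), decision = character()),
       seed = seed, version = LIBRARY_FORMAT_VERSION,
       calibration = list(A = cal$A, B = cal$B))
}

#' Add a user-supplied template from an explicit zinc site
#'
#' Multiplicity and occupancy curation filters are not applied to explicit
#' user templates, only the minimum-residue rule.  Duplicate combinations
#' are allowed (search tries every template).
#'
#' @param library `TemplateLibrary`.
#' @param structure Structure containing the site.
#' @param zinc_index Which zinc het-ion of the structure to use (1-based).
#' @param coordination_cutoff Passed to [extract_observed_sites()].
#' @param min_residues Minimum coordinating residues.
#' @return The library with the new template appended.
#' @export
add_user_template <- function(library, structure, zinc_index = 1L,
                              coordination_cutoff = 2.8, min_residues = 3L) {
  sites <- extract_observed_sites(structure, coordination_cutoff)
  if (zinc_index > length(sites)) {
    stop("structure has no zinc site with index ", zinc_index)
  }
  site <- sites[[zinc_index]]
  if (length(site$residues) < min_residues) {
    stop("user template rejected: only ", length(site$residues),
         " coordinating residue(s), need >= ", min_residues)
  }
  tid <- sprintf("U%03d_%s", length(library$templates) + 1L,
                 paste(.site_combination(site), collapse = "-"))
  library$templates[[length(library$templates) + 1L]] <-
    .site_to_template(site, tid)
  library
}

#' Build the inverted index of a template library
#'
#' Every unordered residue pair of every template is posted under keys
#' (sorted type pair, atom kind in {CA, CB}, integer distance bin
#' `floor(d / bin_width)`).  Queries expand +/- `tolerance_bins` and a pair
#' must match under both the CA and the CB key to count as a hit.
#'
#' @param library `TemplateLibrary`.
#' @param bin_width Distance bin width (Angstrom).
#' @param tolerance_bins Query-time bin tolerance.
#' @return `InvertedIndex` list: `postings` (environment keyed by
#'   "TYPE1|TYPE2|KIND|bin"), `bin_width`, `tolerance_bins`, `templates`
#'   (named list for lookup), `calibration`.
#' @export
build_inverted_index <- function(library, bin_width = 1.0,
                                 tolerance_bins = 1L) {
  postings <- new.env(parent = emptyenv())
  post <- function(key, val) {
    cur <- if (exists(key, envir = postings, inherits = FALSE))
      get(key, envir = postings) else character()
    assign(key, c(cur, val), envir = postings)
  }
  tmap <- list()
  for (tpl in library$templates) {
    tmap[[tpl$template_id]] <- tpl
    k <- length(tpl$residues)
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      ri <- tpl$residues[[i]]; rj <- tpl$residues[[j]]
      if (is.null(ri$ca) || is.null(rj$ca) ||
          is.null(ri$cb) || is.null(rj$cb)) {
        stop("curation error: template ", tpl$template_id,
             " lacks CA/CB for an indexed residue pair")
      }
      types <- sort(c(ri$res_type, rj$res_type))
      slot <- if (ri$res_type <= rj$res_type) c(i, j) else c(j, i)
      val <- paste(tpl$template_id, slot[1], slot[2], sep = "#")
      dca <- .vnorm(ri$ca - rj$ca)
      dcb <- .vnorm(ri$cb - rj$cb)
      post(paste(types[1], types[2], "CA", floor(dca / bin_width), sep = "|"),
           val)
      post(paste(types[1], types[2], "CB", floor(dcb / bin_width), sep = "|"),
           val)
    }
  }
  list(postings = postings, bin_width = bin_width,
       tolerance_bins = as.integer(tolerance_bins), templates = tmap,
       calibration = library$calibration)
}

# All postings for a (sorted) type pair / kind / distance, with tolerance.
.index_lookup <- function(index, type1, type2, kind, distance) {
  b <- floor(distance / index$bin_width)
  bins <- (b - index$tolerance_bins):(b + index$tolerance_bins)
  out <- character()
  for (bb in bins) {
    key <- paste(type1, type2, kind, bb, sep = "|")
    if (exists(key, envir = index$postings, inherits = FALSE)) {
      out <- c(out, get(key, envir = index$postings))
    }
  }
  unique(out)
}

#' Save a template library as versioned JSON
#'
#' @param library `TemplateLibrary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_library <- function(library, path) {
  payload <- list(
    format_version = LIBRARY_FORMAT_VERSION,
    seed = library$seed,
    calibration = library$calibration,
    curation_log = library$curation_log,
    templates = lapply(library$templates, function(t) {
      t$residues <- lapply(t$residues, function(r) {
        r[!vapply(r, is.null, TRUE)]
      })
      t
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a template library from JSON
#'
#' @param path Path written by [save_library()].
#' @return `TemplateLibrary`.
#' @export
load_library <- function(path) {
  payload <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) stop("corrupted library file: ", conditionMessage(e)))
  if (is.null(payload$format_version) ||
      payload$format_version != LIBRARY_FORMAT_VERSION) {
    stop("library format version mismatch: expected ",
         LIBRARY_FORMAT_VERSION, ", found ",
         if (is.null(payload$format_version)) "none" else
           payload$format_version)
  }
  templates <- lapply(payload$templates, function(t) {
    t$combination <- as.character(unlist(t$combination))
    t$zinc_coord <- as.numeric(unlist(t$zinc_coord))
    t$residues <- lapply(t$residues, function(r) {
      for (f in c("coord", "ca", "cb", "bp")) {
        if (!is.null(r[[f]])) r[[f]] <- as.numeric(unlist(r[[f]]))
      }
      r
    })
    t
  })
  log_df <- if (length(payload$curation_log)) {
    do.call(rbind, lapply(payload$curation_log, function(row)
      data.frame(combination = row$combination, n_sites = row$n_sites,
                 n_structures = row$n_structures, decision = row$decision,
                 stringsAsFactors = FALSE)))
  } else {
    data.frame(combination = character(), n_sites = integer(),
               n_structures = integer(), decision = character())
  }
  list(templates = templates, curation_log = log_df,
       seed = payload$seed, version = payload$format_version,
       calibration = list(A = payload$calibration$A,
                          B = payload$calibration$B))
}
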