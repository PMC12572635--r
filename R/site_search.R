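# Candidate-site enumeration: pair collection under the 7 Angstrom rule,
# inverted-index lookup, and backtracking assembly of full combinations.

#' Collect candidate residue pairs of a query structure
#'
#' All unordered pairs of zinc-binding residues whose binding points lie
#' strictly closer than `cutoff`.  Uses a spatial cell grid so the cost is
#' linear in the number of binding residues for bounded site density.
#'
#' @param structure A `ProteinStructure`, or a pre-extracted binding-residue
#'   list.
#' @param cutoff Pair distance cutoff (Angstrom), strict.
#' @return List with `residues` (sorted binding-residue list) and `pairs`
#'   (data frame: i, j indices into `residues`, binding_distance,
#'   ca_distance, cb_distance; NA when CA/CB missing).
#' @export
collect_candidate_pairs <- function(structure, cutoff = 7.0) {
  residues <- if (inherits(structure, "ProteinStructure"))
    extract_binding_residues(structure) else structure
  # deterministic order
  if (length(residues) > 1L) {
    ord <- order(vapply(residues, `[[`, "", "chain"),
                 vapply(residues, function(r) r$seq_id, 0L),
                 vapply(residues, `[[`, "", "icode"))
    residues <- residues[ord]
  }
  n <- length(residues)
  empty <- data.frame(i = integer(), j = integer(),
                      binding_distance = double(), ca_distance = double(),
                      cb_distance = double())
  if (n < 2L) return(list(residues = residues, pairs = empty))
  bp <- do.call(rbind, lapply(residues, `[[`, "bp"))
  # cell grid of side `cutoff`: candidate partners only from the 27
  # neighbouring cells
  cell <- floor(bp / cutoff)
  cell_key <- paste(cell[, 1], cell[, 2], cell[, 3], sep = ",")
  buckets <- split(seq_len(n), cell_key)
  rows <- list()
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (i in seq_len(n)) {
    neigh <- integer()
    for (k in seq_len(nrow(offs))) {
      key <- paste(cell[i, 1] + offs[k, 1], cell[i, 2] + offs[k, 2],
                   cell[i, 3] + offs[k, 3], sep = ",")
      b <- buckets[[key]]
      if (!is.null(b)) neigh <- c(neigh, b)
    }
    neigh <- neigh[neigh > i]
    if (length(neigh) == 0L) next
    d <- sqrt(colSums((t(bp[neigh, , drop = FALSE]) - bp[i, ])^2))
    hit <- neigh[d < cutoff]
    dh <- d[d < cutoff]
    for (m in seq_along(hit)) {
      j <- hit[m]
      ca_d <- if (!is.null(residues[[i]]$ca) && !is.null(residues[[j]]$ca))
        .vnorm(residues[[i]]$ca - residues[[j]]$ca) else NA_real_
      cb_d <- if (!is.null(residues[[i]]$cb) && !is.null(residues[[j]]$cb))
        .vnorm(residues[[i]]$cb - residues[[j]]$cb) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        i = i, j = j, binding_distance = dh[m],
        ca_distance = ca_d, cb_distance = cb_d)
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else empty
  list(residues = residues, pairs = pairs)
}

#' Query the inverted index with candidate pairs
#'
#' A (pair, template-pair-slot) is a hit when the residue types match and
#' both the CA-CA and CB-CB distances fall within the index bin tolerance of
#' the template's.  Hits are returned in both orientations when that is
#' type-consistent, so downstream assembly can map either query residue to
#' either slot.
#'
#' @param candidates Output of [collect_candidate_pairs()].
#' @param index `InvertedIndex` (see [build_inverted_index()]).
#' @return Data frame: `template_id`, `qa`, `qb` (query residue indices),
#'   `slot_a`, `slot_b` (template residue slots matched by qa/qb).
#' @export
query_index <- function(candidates, index) {
  residues <- candidates$residues
  pairs <- candidates$pairs
  empty <- data.frame(template_id = character(), qa = integer(),
                      qb = integer(), slot_a = integer(), slot_b = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L || length(index$templates) == 0L) return(empty)
  rows <- list()
  for (k in seq_len(nrow(pairs))) {
    if (!is.finite(pairs$ca_distance[k]) || !is.finite(pairs$cb_distance[k]))
      next
    i <- pairs$i[k]; j <- pairs$j[k]
    ti <- residues[[i]]$res_type; tj <- residues[[j]]$res_type
    types <- sort(c(ti, tj))
    hits_ca <- .index_lookup(index, types[1], types[2], "CA",
                             pairs$ca_distance[k])
    if (length(hits_ca) == 0L) next
    hits_cb <- .index_lookup(index, types[1], types[2], "CB",
                             pairs$cb_distance[k])
    both <- intersect(hits_ca, hits_cb)
    for (h in both) {
      parts <- strsplit(h, "#", fixed = TRUE)[[1]]
      tid <- parts[1]
      s1 <- as.integer(parts[2]); s2 <- as.integer(parts[3])
      tpl <- index$templates[[tid]]
      t1 <- tpl$residues[[s1]]$res_type; t2 <- tpl$residues[[s2]]$res_type
      # orientations consistent with residue types
      if (ti == t1 && tj == t2) {
        rows[[length(rows) + 1L]] <- data.frame(
          template_id = tid, qa = i, qb = j, slot_a = s1, slot_b = s2,
          stringsAsFactors = FALSE)
      }
      if (ti == t2 && tj == t1) {
        rows[[length(rows) + 1L]] <- data.frame(
          template_id = tid, qa = i, qb = j, slot_a = s2, slot_b = s1,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) unique(do.call(rbind, rows)) else empty
}

#' Assemble candidate sites from pairwise index hits
#'
#' For each template, residue subsets are completed by backtracking over the
#' pair-compatibility graph: the type multiset must equal the template
#' combination, every internal pair must be a hit for its template slot
#' pair, and no residue is used twice in one site.  Duplicate sites (same
#' residue set matched to the same template through different slot
#' assignments) are emitted once.
#'
#' @param hits Output of [query_index()].
#' @param candidates Output of [collect_candidate_pairs()].
#' @param index `InvertedIndex`.
#' @param max_assemblies Combinatorial guard per template; beyond this the
#'   template is skipped with a warning.
#' @return List of `CandidateSite`s: `residues` (binding-residue objects),
#'   `template_id`, `combination`.
#' @export
assemble_candidate_sites <- function(hits, candidates, index,
                                     max_assemblies = 10000L) {
  residues <- candidates$residues
  sites <- list()
  if (nrow(hits) == 0L) return(sites)
  for (tid in unique(hits$template_id)) {
    tpl <- index$templates[[tid]]
    k <- length(tpl$residues)
    th <- hits[hits$template_id == tid, , drop = FALSE]
    # allowed residues per slot, and allowed pairs per slot pair
    slot_cand <- vector("list", k)
    pair_ok <- new.env(parent = emptyenv())
    for (r in seq_len(nrow(th))) {
      slot_cand[[th$slot_a[r]]] <- c(slot_cand[[th$slot_a[r]]], th$qa[r])
      slot_cand[[th$slot_b[r]]] <- c(slot_cand[[th$slot_b[r]]], th$qb[r])
      assign(paste(th$slot_a[r], th$qa[r], th$slot_b[r], th$qb[r]), TRUE,
             envir = pair_ok)
      assign(paste(th$slot_b[r], th$qb[r], th$slot_a[r], th$qa[r]), TRUE,
             envir = pair_ok)
    }
    slot_cand <- lapply(slot_cand, function(v) sort(unique(v)))
    if (any(vapply(slot_cand, length, 0L) == 0L)) next
    n_assembly <- 0L
    overflow <- FALSE
    seen <- new.env(parent = emptyenv())
    assign_rec <- function(slot, chosen) {
      if (overflow) return()
      if (slot > k) {
        n_assembly <<- n_assembly + 1L
        if (n_assembly > max_assemblies) { overflow <<- TRUE; return() }
        key <- paste(sort(chosen), collapse = ",")
        if (!exists(key, envir = seen, inherits = FALSE)) {
          assign(key, TRUE, envir = seen)
          sel <- sort(chosen)
          sites[[length(sites) + 1L]] <<- list(
            residues = residues[sel], template_id = tid,
            combination = tpl$combination)
        }
        return()
      }
      for (q in slot_cand[[slot]]) {
        if (q %in% chosen) next
        ok <- TRUE
        for (prev in seq_len(slot - 1L)) {
          if (!exists(paste(prev, chosen[prev], slot, q), envir = pair_ok,
                      inherits = FALSE)) { ok <- FALSE; break }
        }
        if (ok) assign_rec(slot + 1L, c(chosen, q))
      }
    }
    assign_rec(1L, integer())
    if (overflow) {
      warning("template ", tid, " exceeded ", max_assemblies,
              " raw assemblies; skipped for this structure")
      # drop sites already emitted for this template
      sites <- Filter(function(s) s$template_id != tid, sites)
    }
  }
  sites
}

#' Re-verify a candidate site from scratch
#'
#' Independent check used by tests and the pipeline in paranoid mode:
#' the type multiset must equal the template combination and every internal
#' pair must satisfy the binding-distance cutoff and the CA/CB bin
#' tolerance against some slot pair of the template.
#'
#' @param site `CandidateSite`.
#' @param index `InvertedIndex`.
#' @param cutoff Pair cutoff (Angstrom).
#' @return TRUE or FALSE.
#' @export
verify_candidate_site <- function(site, index, cutoff = 7.0) {
  tpl <- index$templates[[site$template_id]]
  types <- sort(vapply(site$residues, `[[`, "", "res_type"))
  if (!identical(types, sort(as.character(tpl$combination)))) return(FALSE)
  n <- length(site$residues)
  bw <- index$bin_width; tol <- index$tolerance_bins
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ri <- site$residues[[i]]; rj <- site$residues[[j]]
    if (.vnorm(ri$bp - rj$bp) >= cutoff) return(FALSE)
    found <- FALSE
    for (a in seq_along(tpl$residues)) for (b in seq_along(tpl$residues)) {
      if (a == b) next
      ta <- tpl$residues[[a]]; tb <- tpl$residues[[b]]
      if (ta$res_type != ri$res_type || tb$res_type != rj$res_type) next
      dca_t <- .vnorm(ta$ca - tb$ca); dcb_t <- .vnorm(ta$cb - tb$cb)
      dca_q <- .vnorm(ri$ca - rj$ca); dcb_q <- .vnorm(ri$cb - rj$cb)
      if (abs(floor(dca_q / bw) - floor(dca_t / bw)) <= tol &&
          abs(floor(dcb_q / bw) - floor(dcb_t / bw)) <= tol) {
        found <- TRUE; break
      }
    }
    if (!found) return(FALSE)
  }
  TRUE
}
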