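# Synthetic zinc-site structures with exactly known geometry: ideal sites,
# Gaussian-perturbed copies, misoriented His rotamers, decoys, and whole
# synthetic proteins for scaling experiments.  The generator places the
# selected binding atom of every residue exactly at its ideal coordination
# distance from a known ion position, so the placement optimum and all
# score features are analytically known.

.perp_basis <- function(u) {
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  w <- .unit(.cross(u, ref))
  list(w = w, v = .cross(u, w))
}

.random_rotation <- function() {
  # QR-based uniform-ish rotation; only used to decorrelate fixture frames
  M <- matrix(stats::rnorm(9), 3)
  q <- qr.Q(qr(M))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

.atom_row <- function(chain, seq_id, res_type, atom, element, p,
                      occ = 1.0) {
  data.frame(chain = chain, seq_id = seq_id, icode = "", res_type = res_type,
             atom = atom, element = element, x = p[1], y = p[2], z = p[3],
             occ = occ, altloc = "", bfactor = 0, stringsAsFactors = FALSE)
}

# Build one residue whose selected binding atom lies at `zinc + d * u`
# (u: unit direction from the ion).  Side chains extend away from the ion
# with idealised internal geometry; only binding-atom and His-ring positions
# are contract-critical.
.build_residue <- function(res_type, zinc, u, chain, seq_id,
                           his_twist = 0) {
  d <- ideal_distance(res_type, binding_atom_dictionary()[[res_type]][1])
  pb <- .perp_basis(u)
  w <- pb$w; v <- pb$v
  B <- zinc + d * u
  rows <- list()
  add <- function(atom, elem, p) {
    rows[[length(rows) + 1L]] <<- .atom_row(chain, seq_id, res_type, atom,
                                            elem, p)
  }
  if (res_type == "HIS") {
    R <- 1.17  # ring radius for ~1.37 A bonds
    ctr <- zinc + (d + R) * u
    a <- -u  # direction ring centre -> NE2 -> zinc
    ring_at <- function(phi_deg) {
      phi <- phi_deg * pi / 180
      ctr + R * (cos(phi) * a + sin(phi) * v)
    }
    ne2 <- ring_at(0); ce1 <- ring_at(72); nd1 <- ring_at(144)
    cg <- ring_at(216); cd2 <- ring_at(288)
    cg_dir <- .unit(cg - ctr)
    cb <- cg + 1.53 * cg_dir
    ca <- cb + 1.53 * .unit(cg_dir + 0.5 * v)
    if (his_twist != 0) {
      ringm <- rbind(nd1, cd2, ce1, ne2)
      ringm <- .rotate_about_axis(ringm, cg, cg - cb, his_twist)
      nd1 <- ringm[1, ]; cd2 <- ringm[2, ]; ce1 <- ringm[3, ]
      ne2 <- ringm[4, ]
    }
    add("CA", "C", ca); add("CB", "C", cb); add("CG", "C", cg)
    add("ND1", "N", nd1); add("CD2", "C", cd2); add("CE1", "C", ce1)
    add("NE2", "N", ne2)
  } else if (res_type %in% c("GLU", "ASP")) {
    # first carboxylate oxygen at the vertex; the second points away from
    # the ion so atom selection is unambiguous
    o1 <- B
    o2 <- B + 2.2 * .unit(u + w)
    cX <- B + 0.65 * .unit(u - 0.4 * w)        # CD (Glu) / CG (Asp)
    nm <- if (res_type == "GLU") c("OE1", "OE2", "CD", "CG", "CB", "CA") else
      c("OD1", "OD2", "CG", "CB", "CA", NA)
    add(nm[1], "O", o1); add(nm[2], "O", o2); add(nm[3], "C", cX)
    p <- cX
    chain_atoms <- nm[-(1:3)]
    chain_atoms <- chain_atoms[!is.na(chain_atoms)]
    for (i in seq_along(chain_atoms)) {
      p <- p + 1.53 * .unit(u + 0.35 * (if (i %% 2) v else -v))
      add(chain_atoms[i], "C", p)
    }
  } else {
    # single binding atom (Cys SG, Ser OG, Thr OG1, Tyr OH, Asn OD1)
    info <- switch(res_type,
      CYS = list(atom = "SG", elem = "S", stem = 1L),
      SER = list(atom = "OG", elem = "O", stem = 1L),
      THR = list(atom = "OG1", elem = "O", stem = 1L),
      TYR = list(atom = "OH", elem = "O", stem = 3L),
      ASN = list(atom = "OD1", elem = "O", stem = 2L),
      stop("unsupported residue type for ideal site: ", res_type))
    add(info$atom, info$elem, B)
    p <- B
    stems <- c("CB", "CA")
    if (info$stem == 2L) stems <- c("CG", "CB", "CA")
    if (info$stem == 3L) stems <- c("CZ", "CG", "CB", "CA")
    for (i in seq_along(stems)) {
      p <- p + 1.53 * .unit(u + 0.35 * (if (i %% 2) v else -v))
      add(stems[i], "C", p)
    }
  }
  do.call(rbind, rows)
}

.geometry_directions <- function(n, geometry = NULL, apex_height = 1.0,
                                 bond = 2.15) {
  if (is.null(geometry)) {
    geometry <- switch(as.character(n), "3" = "trigonal_apex",
                       "4" = "tetrahedral", "5" = "octahedral_partial",
                       stop("unsupported combination size: ", n))
  }
  switch(geometry,
    tetrahedral = {
      if (n != 4L) stop("tetrahedral geometry needs 4 residues")
      m <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
      m / sqrt(3)
    },
    trigonal_apex = {
      if (n != 3L) stop("trigonal_apex geometry needs 3 residues")
      # ion sits apex_height above the ligand plane
      sin_t <- sqrt(bond^2 - apex_height^2) / bond
      cos_t <- apex_height / bond
      phi <- c(0, 120, 240) * pi / 180
      cbind(sin_t * cos(phi), sin_t * sin(phi), -cos_t)
    },
    octahedral_partial = {
      if (n != 5L) stop("octahedral_partial geometry needs 5 residues")
      rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1))
    },
    stop("unknown geometry: ", geometry)
  )
}

#' Build a structure containing one geometrically ideal zinc site
#'
#' The selected binding atom of every residue is placed exactly at its ideal
#' coordination distance (2.15 Angstrom; 2.32 for Cys S) from the ion, in a
#' tetrahedral, trigonal (ion at the apex above the ligand plane) or partial
#' octahedral arrangement.  His imidazoles are built in-plane pointing at
#' the ion (alpha = beta = 0) unless `his_twist` misorients them about the
#' CB-CG axis.  For His-free 3-residue sites, residue numbering is chosen so
#' the ion lies on side "A" of the ligand plane, matching the deterministic
#' side convention of the placement step.
#'
#' @param combination Character vector (>= 3) of residue types from
#'   [binding_atom_dictionary()].
#' @param geometry NULL (inferred from the combination size) or one of
#'   `"tetrahedral"`, `"trigonal_apex"`, `"octahedral_partial"`.
#' @param zinc Ion position (default origin).
#' @param his_twist Chi2 misorientation in degrees, recycled over His.
#' @param apex_height Trigonal apex height (Angstrom).
#' @param chain Chain identifier.
#' @param structure_id Structure identifier.
#' @param zinc_occupancy Occupancy recorded on the het ion.
#' @return A `ProteinStructure` with the ion as a ZN het-ion; the true ion
#'   position is also stored as attribute `"true_zinc"`.
#' @export
make_ideal_site <- function(combination, geometry = NULL,
                            zinc = c(0, 0, 0), his_twist = 0,
                            apex_height = 1.0, chain = "A",
                            structure_id = "ideal_site",
                            zinc_occupancy = 1.0) {
  combination <- toupper(combination)
  stopifnot(length(combination) >= 3L)
  dirs <- .geometry_directions(length(combination), geometry,
                               apex_height = apex_height)
  twist <- rep_len(his_twist, sum(combination == "HIS"))
  ti <- 0L
  seqs <- 10L * seq_along(combination)
  tabs <- vector("list", length(combination))
  for (i in seq_along(combination)) {
    tw <- 0
    if (combination[i] == "HIS") { ti <- ti + 1L; tw <- twist[ti] }
    tabs[[i]] <- .build_residue(combination[i], zinc, dirs[i, ], chain,
                                seqs[i], his_twist = tw)
  }
  # orient 3-residue numbering so the ion is on side "A"
  if (length(combination) == 3L) {
    bps <- lapply(tabs, function(tb) {
      r <- list(res_type = tb$res_type[1], atoms = tb)
      binding_point(r)
    })
    n <- .cross(bps[[2]] - bps[[1]], bps[[3]] - bps[[1]])
    ctr <- Reduce(`+`, bps) / 3
    if (sum(n * (zinc - ctr)) < 0) {
      # swap numbering of residues 2 and 3 to flip the plane orientation
      tabs <- tabs[c(1, 3, 2)]
      for (i in seq_along(tabs)) tabs[[i]]$seq_id <- seqs[i]
    }
  }
  atoms <- do.call(rbind, tabs)
  rownames(atoms) <- NULL
  het <- data.frame(element = "ZN", x = zinc[1], y = zinc[2], z = zinc[3],
                    occ = zinc_occupancy, stringsAsFactors = FALSE)
  out <- new_protein_structure(structure_id, atoms, het)
  attr(out, "true_zinc") <- zinc
  out
}

#' Rigidly transform a structure (rotation + translation)
#'
#' @param structure A `ProteinStructure`.
#' @param rotation 3x3 rotation matrix (default: random, from the current
#'   RNG stream).
#' @param translation Length-3 shift.
#' @return The transformed structure (true-zinc attribute updated).
#' @export
transform_structure <- function(structure, rotation = NULL,
                                translation = c(0, 0, 0)) {
  if (is.null(rotation)) rotation <- .random_rotation()
  tx <- function(m) sweep(as.matrix(m) %*% t(rotation), 2, -translation)
  a <- structure$atoms
  if (nrow(a) > 0L) a[, c("x", "y", "z")] <- tx(a[, c("x", "y", "z")])
  h <- structure$het_ions
  if (nrow(h) > 0L) h[, c("x", "y", "z")] <- tx(h[, c("x", "y", "z")])
  structure$atoms <- a
  structure$het_ions <- h
  tz <- attr(structure, "true_zinc")
  if (!is.null(tz)) {
    attr(structure, "true_zinc") <- as.numeric(tx(matrix(tz, 1)))
  }
  structure
}

#' Add i.i.d. Gaussian coordinate noise to all protein atoms
#'
#' Emulates predicted-model coordinate error; the het-ion (ground-truth)
#' positions are left untouched.  Deterministic per seed.
#'
#' @param structure A `ProteinStructure`.
#' @param noise_sigma Per-axis standard deviation (Angstrom).
#' @param seed RNG seed.
#' @return The perturbed structure.
#' @export
perturb_site <- function(structure, noise_sigma, seed = 1L) {
  stopifnot(noise_sigma >= 0)
  if (noise_sigma == 0) return(structure)
  a <- structure$atoms
  n <- nrow(a)
  noise <- withr_seed(seed, matrix(stats::rnorm(3 * n, sd = noise_sigma), n))
  a[, c("x", "y", "z")] <- as.matrix(a[, c("x", "y", "z")]) + noise
  structure$atoms <- a
  structure
}

#' Negative-control structures
#'
#' `two_residue`: only two binding residues near a point (below the minimum
#' site size); `stretched`: three binding residues with all pairwise
#' binding-point distances above the 7 Angstrom pair cutoff; `wrong_types`:
#' non-coordinating residues only.
#'
#' @param kind Decoy kind.
#' @param seed RNG seed (orientation of the fragments).
#' @return A `ProteinStructure` with no het ions.
#' @export
make_decoy_site <- function(kind = c("two_residue", "stretched",
                                     "wrong_types"), seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "two_residue") {
    t1 <- .build_residue("HIS", c(0, 0, 0), c(1, 0, 0) / 1, "A", 10L)
    t2 <- .build_residue("GLU", c(0, 0, 0), c(-1, 0, 0), "A", 20L)
    atoms <- rbind(t1, t2)
  } else if (kind == "stretched") {
    centers <- rbind(c(0, 0, 0), c(9, 0, 0), c(4.5, 9, 0))
    tabs <- lapply(1:3, function(i)
      .build_residue(c("HIS", "HIS", "GLU")[i], centers[i, ],
                     c(0, 0, 1), "A", 10L * i))
    atoms <- do.call(rbind, tabs)
  } else {
    rows <- list()
    for (i in 1:4) {
      p <- c(3 * i, 0, 0)
      rows[[i]] <- rbind(
        .atom_row("A", 10L * i, "ALA", "CA", "C", p),
        .atom_row("A", 10L * i, "ALA", "CB", "C", p + c(0, 1.5, 0)))
    }
    atoms <- do.call(rbind, rows)
  }
  rownames(atoms) <- NULL
  new_protein_structure(paste0("decoy_", kind), atoms, .empty_het_table())
}

#' Build a fixture template library from ideal synthetic sites
#'
#' For each residue combination, three ideal sites are generated in three
#' distinct randomly oriented structures (satisfying the curation
#' multiplicity filters) and passed through [curate_templates()].
#'
#' @param specs List of character vectors (residue combinations), or a
#'   single combination.
#' @param seed RNG seed (frames and curation).
#' @return List: `structures` (all generated structures), `library`
#'   (`TemplateLibrary` with one template per combination).
#' @export
make_fixture_library <- function(specs, seed = 1L) {
  if (!is.list(specs)) specs <- list(specs)
  structures <- list()
  sites <- list()
  withr_seed(seed, {
    for (si in seq_along(specs)) {
      for (rep in 1:3) {
        s <- make_ideal_site(specs[[si]],
                             structure_id = sprintf("fix%02d_%d", si, rep))
        s <- transform_structure(s, translation = stats::rnorm(3, sd = 20))
        structures[[length(structures) + 1L]] <- s
      }
    }
  })
  for (s in structures) {
    sites <- c(sites, extract_observed_sites(s))
  }
  library <- curate_templates(sites, seed = seed)
  list(structures = structures, library = library)
}

#' Synthetic protein of arbitrary length for scaling experiments
#'
#' Places `n_residues` along an extended backbone curve, with ideal
#' His-His-Glu-Cys sites grafted on at a fixed rate so the number of true
#' sites grows linearly with length.
#'
#' @param n_residues Total residue count.
#' @param site_every One zinc site per this many residues (default 100).
#' @param seed RNG seed.
#' @return A `ProteinStructure`; true ion positions in the het-ion table.
#' @export
make_synthetic_protein <- function(n_residues, site_every = 100L, seed = 1L) {
  n_sites <- max(1L, n_residues %/% site_every)
  site_len <- 4L
  filler_types <- c("ALA", "GLY", "LEU", "VAL", "PRO")
  rows <- list()
  het <- list()
  withr_seed(seed, {
    seq_id <- 0L
    pos <- c(0, 0, 0)
    site_at <- unique(pmax(1L, round(seq(1, n_residues - site_len,
                                         length.out = n_sites))))
    i <- 1L
    while (i <= n_residues) {
      if (length(site_at) > 0L && i >= site_at[1]) {
        site_at <- site_at[-1]
        zinc <- pos + c(6, 6, 0) + stats::rnorm(3)
        s <- make_ideal_site(c("HIS", "HIS", "GLU", "CYS"), zinc = zinc)
        tb <- s$atoms
        tb$seq_id <- tb$seq_id + seq_id
        rows[[length(rows) + 1L]] <- tb
        het[[length(het) + 1L]] <- s$het_ions
        seq_id <- seq_id + max(s$atoms$seq_id)
        i <- i + site_len
        pos <- pos + c(3.8 * site_len, 0, 0)
        next
      }
      seq_id <- seq_id + 1L
      rt <- sample(filler_types, 1L)
      rows[[length(rows) + 1L]] <- rbind(
        .atom_row("A", seq_id, rt, "CA", "C", pos + stats::rnorm(3, sd = .3)),
        .atom_row("A", seq_id, rt, "CB", "C",
                  pos + c(0, 1.5, 0) + stats::rnorm(3, sd = .3)))
      pos <- pos + c(3.8, 0, 0)
      i <- i + 1L
    }
  })
  atoms <- do.call(rbind, rows)
  rownames(atoms) <- NULL
  hets <- if (length(het)) do.call(rbind, het) else .empty_het_table()
  new_protein_structure(sprintf("synth%d", n_residues), atoms, hets)
}
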