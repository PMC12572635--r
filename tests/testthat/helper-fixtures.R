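# Shared helpers: fabricated residue objects, tiny structure texts, and a
# cached fixture library so expensive generation runs once per session.

fake_residue <- function(res_type, bp, ca = bp + c(3, 0, 0),
                         cb = bp + c(2, 0, 0), chain = "A", seq_id = 1L) {
  list(chain = chain, seq_id = as.integer(seq_id), icode = "",
       res_type = res_type, key = paste(chain, seq_id, "", sep = ":"),
       bp = bp, ca = ca, cb = cb, atoms = NULL)
}

atom_df <- function(chain, seq_id, res_type, atom, element, p, occ = 1,
                    altloc = "") {
  data.frame(chain = chain, seq_id = as.integer(seq_id), icode = "",
             res_type = res_type, atom = atom, element = element,
             x = p[1], y = p[2], z = p[3], occ = occ, altloc = altloc,
             bfactor = 0, stringsAsFactors = FALSE)
}

residue_from_atoms <- function(df) {
  list(chain = df$chain[1], seq_id = df$seq_id[1], icode = "",
       res_type = df$res_type[1],
       key = paste(df$chain[1], df$seq_id[1], "", sep = ":"), atoms = df)
}

# one-His PDB fragment (ND1 + NE2 + ring + CA/CB), plus a ZN het-ion
TINY_HIS_PDB <- c(
  "ATOM      1  CA  HIS A  10       0.000   0.000   0.000  1.00  0.00           C",
  "ATOM      2  CB  HIS A  10       1.530   0.000   0.000  1.00  0.00           C",
  "ATOM      3  CG  HIS A  10       2.300   1.200   0.000  1.00  0.00           C",
  "ATOM      4  ND1 HIS A  10       3.600   1.300   0.000  1.00  0.00           N",
  "ATOM      5  CD2 HIS A  10       1.900   2.500   0.000  1.00  0.00           C",
  "ATOM      6  CE1 HIS A  10       4.000   2.600   0.000  1.00  0.00           C",
  "ATOM      7  NE2 HIS A  10       3.000   3.400   0.000  1.00  0.00           N",
  "HETATM    8 ZN    ZN Z 901       5.000   5.000   0.000  1.00  0.00          ZN",
  "END")

# same content as a minimal mmCIF atom_site loop
TINY_HIS_CIF <- c(
  "data_tiny",
  "loop_",
  "_atom_site.group_PDB",
  "_atom_site.type_symbol",
  "_atom_site.label_atom_id",
  "_atom_site.label_alt_id",
  "_atom_site.auth_comp_id",
  "_atom_site.auth_asym_id",
  "_atom_site.auth_seq_id",
  "_atom_site.pdbx_PDB_ins_code",
  "_atom_site.Cartn_x",
  "_atom_site.Cartn_y",
  "_atom_site.Cartn_z",
  "_atom_site.occupancy",
  "_atom_site.B_iso_or_equiv",
  "_atom_site.pdbx_PDB_model_num",
  "ATOM C CA . HIS A 10 ? 0.000 0.000 0.000 1.00 0.00 1",
  "ATOM C CB . HIS A 10 ? 1.530 0.000 0.000 1.00 0.00 1",
  "ATOM C CG . HIS A 10 ? 2.300 1.200 0.000 1.00 0.00 1",
  "ATOM N ND1 . HIS A 10 ? 3.600 1.300 0.000 1.00 0.00 1",
  "ATOM C CD2 . HIS A 10 ? 1.900 2.500 0.000 1.00 0.00 1",
  "ATOM C CE1 . HIS A 10 ? 4.000 2.600 0.000 1.00 0.00 1",
  "ATOM N NE2 . HIS A 10 ? 3.000 3.400 0.000 1.00 0.00 1",
  "HETATM ZN ZN . ZN Z 901 ? 5.000 5.000 0.000 1.00 0.00 1",
  "#")

# cached fixture library shared across test files (built once)
.fixture_cache <- new.env(parent = emptyenv())

shared_fixture <- function() {
  if (!exists("fix", envir = .fixture_cache)) {
    fix <- make_fixture_library(
      list(c("HIS", "HIS", "GLU", "CYS"),
           c("HIS", "HIS", "GLU"),
           c("ASP", "GLU", "CYS"),
           c("CYS", "CYS", "CYS", "CYS")),
      seed = 7)
    fix$index <- build_inverted_index(fix$library)
    assign("fix", fix, envir = .fixture_cache)
  }
  get("fix", envir = .fixture_cache)
}

expect_coord_equal <- function(a, b, tol = 1e-6) {
  expect_lt(sqrt(sum((a - b)^2)), tol)
}

# Vectorised placement objective over a set of candidate points (rows).
placement_objective <- function(coords, ideals, pts) {
  obj <- 0
  for (i in seq_along(ideals)) {
    d <- sqrt((pts[, 1] - coords[i, 1])^2 + (pts[, 2] - coords[i, 2])^2 +
                (pts[, 3] - coords[i, 3])^2)
    obj <- obj + (d - ideals[i])^2
  }
  obj
}

# Independent oracle: dense two-stage grid search (0.1 A coarse over a
# +/- 3 A box, then 0.01 A fine) for the minimum of the placement objective.
grid_search_zinc <- function(coords, ideals, centre) {
  stage <- function(centre, half, step) {
    ax <- seq(-half, half, by = step)
    g <- as.matrix(expand.grid(ax, ax, ax))
    pts <- sweep(g, 2, -centre)
    vals <- placement_objective(coords, ideals, pts)
    list(pos = pts[which.min(vals), ], obj = min(vals))
  }
  s1 <- stage(centre, 3, 0.1)
  s2 <- stage(s1$pos, 0.12, 0.01)
  s2
}

# Placement exactly as the pipeline runs it: centroid start for 4+ ligands,
# both mirrored starts (keeping the better) for 3.
lm_placement <- function(coords, ideals) {
  chosen <- lapply(seq_along(ideals), function(i)
    list(res_type = "X", atom = "X", coord = coords[i, ],
         d_ideal = ideals[i]))
  starts <- if (length(ideals) == 3L)
    initial_zinc_estimate(lapply(seq_len(3), function(i) coords[i, ]))
  else list(colMeans(coords))
  pls <- lapply(starts, function(s0) refine_zinc_position(chosen, s0))
  pls[[which.min(vapply(pls, `[[`, 0, "objective"))]]
}
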