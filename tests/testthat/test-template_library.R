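# Helper: a synthetic observed site without going through a structure.
fake_site <- function(combo, source_id, occ = 1, center = c(0, 0, 0)) {
  st <- make_ideal_site(combo, zinc = center, structure_id = source_id,
                        zinc_occupancy = occ)
  sites <- extract_observed_sites(st)
  expect_length(sites, 1L)
  sites[[1]]
}

test_that("extract_observed_sites finds coordinating residues within cutoff", {
  st <- make_ideal_site(c("HIS", "HIS", "GLU", "CYS"))
  sites <- extract_observed_sites(st)
  expect_length(sites, 1L)
  s <- sites[[1]]
  expect_length(s$residues, 4L)
  d <- vapply(s$chosen, function(ch) sqrt(sum((ch$coord - s$zinc_coord)^2)), 0)
  ideal <- vapply(s$chosen, `[[`, 0, "d_ideal")
  expect_equal(d, ideal, tolerance = 1e-9)
  # moving the ion away from one residue drops it from the coordination set
  st2 <- st
  st2$het_ions[1, c("x", "y", "z")] <- s$zinc_coord + c(0, 0, 1.4)
  s2 <- extract_observed_sites(st2)[[1]]
  expect_lt(length(s2$residues), 4L)
  # zinc-free structure: no sites
  st3 <- st
  st3$het_ions <- st3$het_ions[0, ]
  expect_length(extract_observed_sites(st3), 0L)
})

test_that("two nearby zincs share a bridging residue", {
  atoms <- rbind(
    atom_df("A", 1, "ASP", "OD1", "O", c(1.8, 1.0, 0)),  # bridging
    atom_df("A", 2, "HIS", "NE2", "N", c(-2.15, 0, 0)),
    atom_df("A", 3, "HIS", "NE2", "N", c(0, -2.15, 0)),
    atom_df("A", 4, "CYS", "SG", "S", c(5.75, 0, 0)),
    atom_df("A", 5, "SER", "OG", "O", c(3.6, -2.15, 0)))
  het <- data.frame(element = c("ZN", "ZN"), x = c(0, 3.6), y = 0, z = 0,
                    occ = 1, stringsAsFactors = FALSE)
  st <- znsight:::new_protein_structure("bi", atoms, het)
  sites <- extract_observed_sites(st)
  expect_length(sites, 2L)
  in_both <- vapply(sites, function(s)
    any(vapply(s$residues, `[[`, "", "res_type") == "ASP"), TRUE)
  expect_true(all(in_both))
})

test_that("curation applies the three filters exactly", {
  sites <- c(
    # accepted: 3 sites in 3 distinct structures, occ 1
    lapply(1:3, function(i) fake_site(c("HIS", "HIS", "GLU"),
                                      sprintf("s%d", i))),
    # rejected: 4 sites but only 2 structures
    lapply(1:4, function(i) fake_site(c("CYS", "CYS", "CYS", "CYS"),
                                      sprintf("t%d", (i %% 2) + 1))),
    # rejected: occupancy 0.4 site never counted, leaving only 2 sites
    list(fake_site(c("ASP", "GLU", "SER"), "u1", occ = 0.4),
         fake_site(c("ASP", "GLU", "SER"), "u2"),
         fake_site(c("ASP", "GLU", "SER"), "u3")))
  lib <- curate_templates(sites, seed = 5)
  combos <- vapply(lib$templates, function(t)
    paste(t$combination, collapse = ","), "")
  expect_equal(combos, "GLU,HIS,HIS")
  log <- lib$curation_log
  expect_equal(log$decision[log$combination == "CYS,CYS,CYS,CYS"],
               "rejected: 2 structure(s) < 3")
  expect_match(log$decision[log$combination == "ASP,GLU,SER"], "2 site")
  # occupancy filter: raising occupancy flips the decision
  sites2 <- c(sites[1:7],
              lapply(1:3, function(i) fake_site(c("ASP", "GLU", "SER"),
                                                sprintf("u%d", i))))
  lib2 <- curate_templates(sites2, seed = 5)
  expect_setequal(
    vapply(lib2$templates, function(t) paste(t$combination, collapse = ","),
           ""),
    c("GLU,HIS,HIS", "ASP,GLU,SER"))
  # sites with fewer than 3 residues are dropped before counting
  small <- fake_site(c("HIS", "HIS", "GLU"), "v1")
  small$residues <- small$residues[1:2]
  expect_length(curate_templates(list(small, small, small))$templates, 0L)
})

test_that("curation is deterministic in seed and order-invariant in outcome", {
  sites <- lapply(1:4, function(i)
    fake_site(c("HIS", "HIS", "GLU"), sprintf("s%d", i), center = c(i, 0, 0)))
  lib_a <- curate_templates(sites, seed = 42)
  lib_b <- curate_templates(sites, seed = 42)
  expect_equal(lib_a$templates[[1]]$source_id, lib_b$templates[[1]]$source_id)
  lib_c <- curate_templates(rev(sites), seed = 42)
  expect_equal(
    vapply(lib_c$templates, function(t) paste(t$combination, collapse = ","),
           ""),
    vapply(lib_a$templates, function(t) paste(t$combination, collapse = ","),
           ""))
})

test_that("inverted index: posting count and binning arithmetic", {
  fix <- make_fixture_library(list(c("HIS", "HIS", "GLU")), seed = 1)
  idx <- build_inverted_index(fix$library)
  # 3 residues -> 3 pairs x 2 atom kinds = 6 postings
  keys <- ls(envir = idx$postings)
  n_postings <- sum(vapply(keys, function(k)
    length(get(k, envir = idx$postings)), 0L))
  expect_equal(n_postings, 6L)
  # bin arithmetic: query 6.4 vs template 6.9 hits (bins 6 vs 6);
  # query 4.1 vs 6.9 misses (bins 4 vs 6, tolerance 1)
  tpl_pair <- get(grep("\\|CA\\|", keys, value = TRUE)[1],
                  envir = idx$postings)
  key_parts <- strsplit(grep("\\|CA\\|", keys, value = TRUE)[1], "\\|")[[1]]
  t1 <- key_parts[1]; t2 <- key_parts[2]
  bin <- as.integer(key_parts[4])
  d_in <- bin + 0.4
  expect_true(length(znsight:::.index_lookup(idx, t1, t2, "CA", d_in)) > 0)
  expect_length(znsight:::.index_lookup(idx, t1, t2, "CA", d_in - 2.3), 0L)
})

test_that("index lookup equals brute-force bin comparison (oracle)", {
  fix <- shared_fixture()
  idx <- fix$index
  set.seed(11)
  for (rep in 1:25) {
    tpl <- fix$library$templates[[sample(length(fix$library$templates), 1)]]
    i <- sample(length(tpl$residues), 2)
    ra <- tpl$residues[[i[1]]]; rb <- tpl$residues[[i[2]]]
    d_query <- runif(1, 2, 12)
    types <- sort(c(ra$res_type, rb$res_type))
    hits <- znsight:::.index_lookup(idx, types[1], types[2], "CA", d_query)
    # oracle: scan all template pairs directly
    brute <- character()
    for (t2 in fix$library$templates) {
      k <- length(t2$residues)
      for (a in seq_len(k - 1)) for (b in (a + 1):k) {
        p1 <- t2$residues[[a]]; p2 <- t2$residues[[b]]
        if (!setequal(c(p1$res_type, p2$res_type), unique(types)) ||
            !identical(sort(c(p1$res_type, p2$res_type)), types)) next
        dab <- sqrt(sum((p1$ca - p2$ca)^2))
        if (abs(floor(dab / idx$bin_width) -
                floor(d_query / idx$bin_width)) <= idx$tolerance_bins) {
          slot <- if (p1$res_type <= p2$res_type) c(a, b) else c(b, a)
          brute <- c(brute, paste(t2$template_id, slot[1], slot[2],
                                  sep = "#"))
        }
      }
    }
    expect_setequal(hits, unique(brute))
  }
})

test_that("user templates bypass multiplicity filters", {
  fix <- shared_fixture()
  lib <- fix$library
  n0 <- length(lib$templates)
  st <- make_ideal_site(c("ASP", "ASP", "TYR"), structure_id = "user1")
  lib2 <- add_user_template(lib, st)
  expect_length(lib2$templates, n0 + 1L)
  expect_equal(lib2$templates[[n0 + 1]]$combination,
               c("ASP", "ASP", "TYR"))
  # duplicate combination allowed, distinct id
  lib3 <- add_user_template(lib2, st)
  expect_length(lib3$templates, n0 + 2L)
  ids <- vapply(lib3$templates, `[[`, "", "template_id")
  expect_false(anyDuplicated(ids) > 0)
  # a 2-residue site is rejected
  two <- make_decoy_site("two_residue")
  two$het_ions <- data.frame(element = "ZN", x = 0, y = 0, z = 0, occ = 1)
  expect_error(add_user_template(lib, two), "coordinating residue")
})

test_that("library JSON round-trip is lossless and versioned", {
  fix <- shared_fixture()
  path <- withr::local_tempfile(fileext = ".json")
  save_library(fix$library, path)
  lib2 <- load_library(path)
  expect_length(lib2$templates, length(fix$library$templates))
  for (i in seq_along(lib2$templates)) {
    a <- fix$library$templates[[i]]; b <- lib2$templates[[i]]
    expect_equal(a$template_id, b$template_id)
    expect_equal(a$combination, b$combination)
    expect_equal(a$zinc_coord, b$zinc_coord, tolerance = 1e-12)
    for (j in seq_along(a$residues)) {
      expect_equal(a$residues[[j]]$coord, b$residues[[j]]$coord,
                   tolerance = 1e-12)
      expect_equal(a$residues[[j]]$ca, b$residues[[j]]$ca, tolerance = 1e-12)
    }
  }
  expect_equal(lib2$calibration$A, fix$library$calibration$A)
  # corrupted file and version mismatch raise
  writeLines("{not json", path)
  expect_error(load_library(path), "corrupted")
  jsonlite::write_json(list(format_version = 99), path, auto_unbox = TRUE)
  expect_error(load_library(path), "version mismatch")
})
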