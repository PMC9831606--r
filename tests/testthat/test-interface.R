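test_that("multi-model coordinate files parse into frames", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(mini_pdb_text(), tf)
  fr <- read_frames(tf)
  expect_s3_class(fr, "frame_list")
  expect_length(fr, 3L)
  expect_true(all(vapply(fr, nrow, 1L) == 4L))
  expect_equal(fr[[2]]$x[1], 0.1)
  expect_setequal(unique(fr[[1]]$chain), c("E", "A", "W", "L"))
  expect_equal(attr(fr[[3]], "frame_index"), 3L)
  expect_false(any(fr[[1]]$is_hydrogen))

  # single-model file (no MODEL records) yields one frame
  writeLines(mini_pdb_text()[2:5], tf)
  expect_length(read_frames(tf), 1L)

  # truncated coordinate field is rejected with its line number
  bad <- mini_pdb_text()
  bad[3] <- substr(bad[3], 1, 40)
  writeLines(bad, tf)
  expect_error(read_frames(tf), "line 3")

  writeLines(c("REMARK nothing", "END"), tf)
  expect_error(read_frames(tf), "no ATOM/HETATM")
})

test_that("atoms classify into environment groups by chain and residue rules", {
  fr <- make_frame(
    chain = c("E", "A", "W", "L", "L", "I", "Q"),
    resno = 1:7,
    resid = c("ALA", "GLY", "HOH", "POPC", "POPC", "SOD", "UNK"),
    elety = c("CA", "CA", "O", "P", "C216", "SOD", "ZZ"),
    elesy = c("C", "C", "O", "P", "C", "NA", "X"),
    x = 1:7, y = 0, z = 0)
  g <- classify_atoms(fr)
  expect_equal(g, c("peptide", "channel", "water", "lipid_head", "lipid_tail",
                    "ion", "other"))
  no_pep <- make_frame("A", 1, "GLY", "CA", "C", 0, 0, 0)
  expect_error(classify_atoms(no_pep), "no peptide chain")
})

test_that("group rules serialize to a config file and back", {
  r <- group_rules(peptide_chains = "P", channel_chains = c("A", "B"))
  tf <- withr::local_tempfile(fileext = ".yaml")
  write_group_rules(r, tf)
  expect_equal(read_group_rules(tf), r)
})

test_that("fractional contacts are exact count ratios with planted extremes", {
  # residue 1 always within cutoff of the lipid head, never near water
  mk <- function(idx) make_frame(
    chain = c("E", "A", "L", "W"),
    resno = c(1, 1, 50, 60),
    resid = c("ALA", "ALA", "POPC", "HOH"),
    elety = c("CA", "CA", "P", "O"),
    elesy = c("C", "C", "P", "O"),
    x = c(0, 3.0, 0, 0), y = c(0, 0, 3.0, 30), z = 0,
    frame_index = idx)
  frames <- structure(lapply(1:4, mk), class = "frame_list")
  prof <- fractional_contacts(frames, params = contact_params(chain_pairs = "A:E"))
  expect_equal(prof$values["1", "lipid_head"], 1.0)
  expect_equal(prof$values["1", "channel"], 1.0)
  expect_equal(prof$values["1", "water"], 0.0)
  expect_equal(prof$n_observations, 4L)
  expect_identical(prof$counts / prof$n_observations, prof$values)

  # re-running is bit-identical
  expect_identical(
    fractional_contacts(frames, params = contact_params(chain_pairs = "A:E")),
    prof)

  expect_error(contact_params(chain_pairs = character(0)))
  expect_error(
    fractional_contacts(frames, params = contact_params(chain_pairs = "B:Z")),
    "absent")
})

test_that("increasing the cutoff never decreases a fractional contact", {
  txt <- gen_complex_frames(n_frames = 8, peptide_length = 3,
                            contact_probs = 0.5, seed = 303)
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(txt, tf)
  fr <- read_frames(tf)
  prev <- NULL
  for (cut in c(2.0, 3.5, 6.0, 9.0)) {
    prof <- fractional_contacts(fr, params = contact_params(cutoff = cut))
    if (!is.null(prev)) expect_true(all(prof$values >= prev - 1e-15))
    prev <- prof$values
  }
})

test_that("cell-list search equals the all-pairs brute force exactly", {
  set.seed(99)
  for (k in 1:6) {
    a <- matrix(runif(3 * sample(5:40, 1), 0, 15), ncol = 3)
    b <- matrix(runif(3 * sample(5:40, 1), 0, 15), ncol = 3)
    cut <- runif(1, 1, 6)
    pc <- pairs_within(a, b, cut, method = "cell")
    pb <- pairs_within(a, b, cut, method = "brute")
    expect_same_pairs(pc, pb)
    # pair symmetry: searching group -> residue finds the transposed pairs
    rev <- pairs_within(b, a, cut, method = "cell")
    expect_same_pairs(pc, data.frame(i = rev$j, j = rev$i, dist = rev$dist))
  }
})

test_that("profiles agree between search backends on generated frames", {
  txt <- gen_complex_frames(n_frames = 6, peptide_length = 3,
                            contact_probs = 0.4, seed = 17)
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(txt, tf)
  fr <- read_frames(tf)
  pc <- fractional_contacts(fr, params = contact_params(method = "cell"))
  pb <- fractional_contacts(fr, params = contact_params(method = "brute"))
  expect_identical(pc$values, pb$values)
})

test_that("hydrogen bonds and salt bridges are found by geometric criteria", {
  # backbone N at 2.9 A from a backbone O
  hb <- make_frame(chain = c("E", "A"), resno = c(1, 10),
                   resid = c("ALA", "GLY"), elety = c("N", "O"),
                   elesy = c("N", "O"), x = c(0, 2.9), y = 0, z = 0)
  got <- find_polar_interactions(hb, "hbond")
  expect_equal(nrow(got), 1L)
  expect_equal(got$distance, 2.9)
  expect_equal(got$atom1, "N"); expect_equal(got$atom2, "O")

  far <- hb; far$x[2] <- 3.6
  expect_equal(nrow(find_polar_interactions(far, "hbond")), 0L)

  # arginine guanidinium N 3.4 A from an aspartate carboxylate O
  sb <- make_frame(chain = c("E", "A"), resno = c(20, 816),
                   resid = c("ARG", "ASP"), elety = c("NH1", "OD1"),
                   elesy = c("N", "O"), x = c(0, 3.4), y = 0, z = 0)
  got <- find_polar_interactions(sb, "salt_bridge")
  expect_equal(nrow(got), 1L)
  expect_equal(got$kind, "salt_bridge")
  expect_equal(got$distance, 3.4)
  # but not an hbond pairing (NH1 is not in the donor->acceptor direction here)
  expect_equal(nrow(find_polar_interactions(sb, "salt_bridge",
                                            criteria = list(salt_bridge = 3.0))),
               0L)

  expect_error(find_polar_interactions(hb, "pi_stack"))
})

test_that("explicit hydrogens enforce the donor angle criterion", {
  # donor N with H pointing toward the acceptor: angle 180, accepted
  lin <- make_frame(chain = c("E", "E", "A"), resno = c(1, 1, 10),
                    resid = c("ALA", "ALA", "GLY"),
                    elety = c("N", "H", "O"), elesy = c("N", "H", "O"),
                    x = c(0, 1.0, 2.9), y = 0, z = 0)
  expect_equal(nrow(find_polar_interactions(lin, "hbond")), 1L)
  # H at right angle to the N...O axis: angle ~71 degrees, rejected
  bent <- lin
  bent$x[2] <- 0; bent$y[2] <- 1.0
  expect_equal(nrow(find_polar_interactions(bent, "hbond")), 0L)
})

test_that("interface-only filtering keeps peptide-channel pairs", {
  fr <- make_frame(chain = c("E", "A", "W"), resno = c(1, 10, 99),
                   resid = c("ARG", "ASP", "HOH"),
                   elety = c("NH1", "OD1", "O"), elesy = c("N", "O", "O"),
                   x = c(0, 3.4, 2.8), y = 0, z = 0)
  all_hits <- find_polar_interactions(fr, "hbond")
  iface <- find_polar_interactions(fr, "hbond", interface_only = TRUE)
  expect_true(nrow(iface) < nrow(all_hits))
  expect_true(all(iface$chain2 %in% c("A", "E")))
})
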