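# Shared fixtures and independent oracles.

table5_variants <- function() {
  parse_variant_table(knotopt_file("ptx2_variants.tsv"))
}

# Independent brute-force oracle for the two-stage selection cascade:
# repeated minimum extraction with explicit (value, tag) tie-break, no use of
# order()/sort().
oracle_cascade <- function(records, n_score, n_ddg) {
  extract_min <- function(d, col, n) {
    out <- d[0, , drop = FALSE]
    while (nrow(out) < n && nrow(d) > 0L) {
      best <- 1L
      for (i in seq_len(nrow(d))) {
        if (d[[col]][i] < d[[col]][best] ||
            (d[[col]][i] == d[[col]][best] && d$tag[i] < d$tag[best]))
          best <- i
      }
      out <- rbind(out, d[best, , drop = FALSE])
      d <- d[-best, , drop = FALSE]
    }
    out
  }
  s1 <- extract_min(records, "total_score", min(n_score, nrow(records)))
  s2 <- extract_min(s1, "ddg", min(n_ddg, nrow(s1)))
  rownames(s2) <- NULL
  s2
}

# Build a structure_frame directly from atom vectors (bypasses file I/O for
# geometric unit tests).
make_frame <- function(chain, resno, resid, elety, elesy, x, y, z,
                       frame_index = 1L) {
  ish <- toupper(elesy) %in% c("H", "D")
  fr <- data.frame(chain = chain, resno = as.integer(resno), resid = resid,
                   elety = elety, elesy = elesy, is_hydrogen = ish,
                   x = x, y = y, z = z, stringsAsFactors = FALSE)
  attr(fr, "frame_index") <- frame_index
  class(fr) <- c("structure_frame", "data.frame")
  fr
}

# Hand-written three-model coordinate fixture: one peptide residue (chain E),
# one channel atom (chain A), one water, one lipid head atom.
mini_pdb_text <- function() {
  mk <- function(model, dx) c(
    sprintf("MODEL %8d", model),
    sprintf("ATOM      1  CA  ALA E   1    %8.3f%8.3f%8.3f  1.00  0.00           C", 0 + dx, 0, 0),
    sprintf("ATOM      2  CA  GLY A  10    %8.3f%8.3f%8.3f  1.00  0.00           C", 3 + dx, 0, 0),
    sprintf("HETATM    3  O   HOH W 100    %8.3f%8.3f%8.3f  1.00  0.00           O", 0 + dx, 8, 0),
    sprintf("HETATM    4  P   POPCL 200    %8.3f%8.3f%8.3f  1.00  0.00           P", 0 + dx, 0, 2.5),
    "ENDMDL")
  c(mk(1, 0), mk(2, 0.1), mk(3, 0.2), "END")
}

# Closed-form time-average of a * (1 - exp(-t/tau_a)) * exp(-t/tau_i) over
# [t0, t1] (t measured from step onset): the analytic window-mean oracle.
analytic_window_mean <- function(amp, tau_act, tau_inact, t0, t1) {
  beta <- 1 / tau_inact
  gam <- 1 / tau_act + 1 / tau_inact
  I <- (exp(-beta * t0) - exp(-beta * t1)) / beta -
    (exp(-gam * t0) - exp(-gam * t1)) / gam
  amp * I / (t1 - t0)
}

expect_same_pairs <- function(p1, p2) {
  k1 <- paste(p1$i, p1$j)
  k2 <- paste(p2$i, p2$j)
  expect_setequal(k1, k2)
  expect_equal(p1$dist[order(k1)], p2$dist[order(k2)])
}
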