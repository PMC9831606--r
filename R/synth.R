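.pdb_line <- function(type, serial, name, resid, chain, resno, x, y, z, element) {
  name4 <- ifelse(nchar(name) >= 4L, substr(name, 1, 4),
                  sprintf(" %-3s", name))
  sprintf("%-6s%5d %-4s%1s%-4s%1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, name4, "", sprintf("%-4s", resid), chain, resno, "",
          x, y, z, 1.0, 0.0, sprintf("%2s", element))
}

.FRAME_GROUPS <- c("lipid_head", "lipid_tail", "water", "channel")

#' Generate multi-model frames with planted residue-group contacts
#'
#' Emits PDB-dialect text for `n_frames` frames of a minimal
#' peptide/channel/membrane system in which, for every (frame, chain-pair,
#' residue, group) observation, a single pseudo-atom of the group is placed
#' 2.5 Angstrom from the residue with the planted probability and 8.0
#' Angstrom away otherwise. Residue and chain naming follow the default
#' [group_rules()] (POPC lipid with head `P` / tail `C28` atoms, HOH water,
#' channel chains A-D, peptide chains E-H), so [fractional_contacts()]
#' recovers the planted probabilities with binomial sampling error. The
#' geometry is deliberately minimal — one placement per observation, with
#' residues and pairs spaced far beyond the cutoff — so planted contact
#' states can never collide; realism is not the goal, classifiability and a
#' known truth are.
#'
#' @param n_frames Number of frames.
#' @param peptide_length Residues per peptide chain.
#' @param contact_probs Either a single probability applied everywhere or a
#'   `peptide_length` x 4 matrix with columns `lipid_head`, `lipid_tail`,
#'   `water`, `channel`.
#' @param chain_pairs `"channel:peptide"` pair strings (default the
#'   four-fold `A:E ... D:H` layout).
#' @param seed Seed (fanned out via [derive_seed()]).
#' @param path Optional output file; when NULL the lines are returned.
#' @return Character vector of PDB lines (invisibly when `path` given).
#' @export
gen_complex_frames <- function(n_frames, peptide_length, contact_probs,
                               chain_pairs = c("A:E", "B:F", "C:G", "D:H"),
                               seed = 1, path = NULL) {
  if (is.matrix(contact_probs)) {
    stopifnot(nrow(contact_probs) == peptide_length,
              all(.FRAME_GROUPS %in% colnames(contact_probs)))
    pm <- contact_probs[, .FRAME_GROUPS, drop = FALSE]
  } else {
    stopifnot(length(contact_probs) == 1L)
    pm <- matrix(contact_probs, peptide_length, 4,
                 dimnames = list(NULL, .FRAME_GROUPS))
  }
  if (any(pm < 0 | pm > 1)) stop("contact probabilities must lie in [0, 1]")
  pr <- strsplit(chain_pairs, ":", fixed = TRUE)
  cchains <- vapply(pr, `[`, "", 1L)
  pchains <- vapply(pr, `[`, "", 2L)
  npairs <- length(pr)
  near <- 2.5; far <- 8.0
  # fixed anchor layout: pairs 100 A apart, residues 20 A apart
  dirs <- rbind(lipid_head = c(0, 1, 0), lipid_tail = c(0, -1, 0),
                water = c(0, 0, 1), channel = c(0, 0, -1))
  lines <- with_seed(derive_seed(seed, "frames"), {
    out <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      fl <- character(0)
      serial <- 0L
      for (k in seq_len(npairs)) {
        ox <- (k - 1) * 100
        for (i in seq_len(peptide_length)) {
          anchor <- c(ox + (i - 1) * 20, 0, 0)
          serial <- serial + 1L
          fl <- c(fl, .pdb_line("ATOM", serial, "CA", "ALA", pchains[k], i,
                                anchor[1], anchor[2], anchor[3], "C"))
          molno <- (k - 1L) * peptide_length + i
          for (g in .FRAME_GROUPS) {
            d <- if (stats::runif(1) < pm[i, g]) near else far
            p <- anchor + dirs[g, ] * d
            serial <- serial + 1L
            fl <- c(fl, switch(
              g,
              lipid_head = .pdb_line("HETATM", serial, "P", "POPC", "L",
                                     molno, p[1], p[2], p[3], "P"),
              lipid_tail = .pdb_line("HETATM", serial, "C28", "POPC", "L",
                                     molno, p[1], p[2], p[3], "C"),
              water = .pdb_line("HETATM", serial, "O", "HOH", "W",
                                molno, p[1], p[2], p[3], "O"),
              channel = .pdb_line("ATOM", serial, "CA", "ALA", cchains[k], i,
                                  p[1], p[2], p[3], "C")
            ))
          }
        }
      }
      out[[f]] <- c(sprintf("MODEL %8d", f), fl, "ENDMDL")
    }
    c(unlist(out), "END")
  })
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Generate a synthetic design scorefile
#'
#' Emits `SCORE:`-dialect text for `n_designs` records with jointly normal
#' `total_score` and `ddg` at the given correlation, random sequences over
#' the alphabet, and — when a motif is planted — a guaranteed enrichment of
#' the motif residues among the records the two-stage cascade
#' ([select_designs()] with the same `n_score`/`n_ddg`) will retain:
#' `ceiling(enrichment * n_ddg)` of the cascade winners carry the motif
#' exactly, so a consensus over the selected set recovers it.
#'
#' @param n_designs Number of records (default 1000).
#' @param total_mean,total_sd,ddg_mean,ddg_sd Score model (energies, lower
#'   is better).
#' @param correlation Correlation between total score and interface energy.
#' @param peptide_length Sequence length (default 30).
#' @param alphabet Residue alphabet.
#' @param planted_motif Optional named character vector, names = positions,
#'   values = residues (e.g. `c("20" = "R", "28" = "E")`).
#' @param enrichment Fraction of cascade winners guaranteed to carry the
#'   motif (default 0.9).
#' @param n_score,n_ddg Cascade sizes used to identify the winner set for
#'   motif planting.
#' @param seed Seed.
#' @param path Optional output path.
#' @return Character vector of scorefile lines.
#' @export
gen_scorefile <- function(n_designs = 1000, total_mean = -300, total_sd = 10,
                          ddg_mean = -30, ddg_sd = 5, correlation = 0.5,
                          peptide_length = 30, alphabet = .CANONICAL_AA,
                          planted_motif = NULL, enrichment = 0.9,
                          n_score = 100, n_ddg = 20, seed = 1, path = NULL) {
  stopifnot(abs(correlation) <= 1)
  lines <- with_seed(derive_seed(seed, "scorefile"), {
    z1 <- stats::rnorm(n_designs); z2 <- stats::rnorm(n_designs)
    total <- total_mean + total_sd * z1
    ddg <- ddg_mean + ddg_sd * (correlation * z1 +
                                  sqrt(1 - correlation^2) * z2)
    tag <- sprintf("design_%05d", seq_len(n_designs))
    seqm <- matrix(sample(alphabet, n_designs * peptide_length, replace = TRUE),
                   nrow = n_designs)
    if (!is.null(planted_motif) && n_designs >= 1L) {
      o1 <- order(total, tag)[seq_len(min(n_score, n_designs))]
      o2 <- o1[order(ddg[o1], tag[o1])[seq_len(min(n_ddg, length(o1)))]]
      carriers <- o2[seq_len(ceiling(enrichment * length(o2)))]
      for (p in names(planted_motif))
        seqm[carriers, as.integer(p)] <- planted_motif[[p]]
    }
    seqs <- apply(seqm, 1, paste, collapse = "")
    c("SCORE: total_score ddg sequence description",
      sprintf("SCORE: %.3f %.3f %s %s", total, ddg, seqs, tag))
  })
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Generate synthetic concentration-response data
#'
#' Draws per-cell fractional inhibition from the Hill model
#' `f = [L]^h / (IC50^h + [L]^h)` plus Gaussian noise truncated (clipped) to
#' `[0, 1]`. Defaults mirror a typical manual patch-clamp potency assay:
#' a half-log concentration ladder spanning the IC50 and three cells.
#'
#' @param ic50 True IC50 in nM (default 7).
#' @param h True Hill coefficient (default 1).
#' @param concentrations Concentration ladder in nM.
#' @param noise_sd SD of the additive Gaussian noise (default 0.05).
#' @param n_cells Cells per concentration (default 3).
#' @param seed Seed; NULL uses the current RNG stream.
#' @param peptide,subtype Optional identifiers carried into the output.
#' @return A data.frame of class `dose_response` with columns
#'   `concentration_nM`, `fraction_inhibited`, `cell_id` (and `peptide`,
#'   `subtype` if given).
#' @export
gen_dose_response <- function(ic50 = 7, h = 1,
                              concentrations = c(1, 3, 10, 30, 100),
                              noise_sd = 0.05, n_cells = 3, seed = NULL,
                              peptide = NULL, subtype = NULL) {
  stopifnot(ic50 > 0, h > 0, all(concentrations > 0))
  run <- function() {
    conc <- rep(concentrations, times = n_cells)
    cell <- rep(seq_len(n_cells), each = length(concentrations))
    f <- .hill(conc, ic50, h)
    if (noise_sd > 0) f <- f + stats::rnorm(length(f), 0, noise_sd)
    f <- pmin(1, pmax(0, f))
    out <- data.frame(concentration_nM = conc, fraction_inhibited = f,
                      cell_id = cell)
    if (!is.null(peptide)) out$peptide <- peptide
    if (!is.null(subtype)) out$subtype <- subtype
    class(out) <- c("dose_response", "data.frame")
    out
  }
  if (is.null(seed)) run() else with_seed(derive_seed(seed, "dose_response"), run())
}

#' Generate a synthetic per-cell excitability table
#'
#' Emulates a dose-escalation current-clamp experiment: each cell has a
#' baseline rheobase drawn uniformly from `baseline_rheobase_range`, each
#' dose multiplies rheobase by a planted factor (with small multiplicative
#' noise) and thins the AP trains binomially with a per-frequency survival
#' probability. Stimulus counts are 10 at 0.1 Hz and 120 at 1, 3, 10 Hz.
#' Default dose effects follow the graded profile typical of a selective
#' sodium-channel blocker: little effect at 0.01 uM, partial failure at
#' 0.1 uM and strong suppression plus a ~50% rheobase rise at 1 uM.
#'
#' @param n_cells Number of cells (default 10).
#' @param baseline_rheobase_range Range of baseline rheobase in pA.
#' @param dose_effects Named list (names = dose labels) of
#'   `list(rheo_mult =, surv = c(...))` with one survival probability per
#'   frequency (0.1, 1, 3, 10 Hz).
#' @param rheo_noise_sd SD of the multiplicative log-normal rheobase noise.
#' @param seed Seed.
#' @param path Optional CSV output path.
#' @return An `ephys_cells` data.frame (see [read_ephys_cells()]).
#' @export
gen_ephys_table <- function(n_cells = 10,
                            baseline_rheobase_range = c(300, 2000),
                            dose_effects = list(
                              "0.01" = list(rheo_mult = 1.05,
                                            surv = c(1, 1, 0.83, 0.58)),
                              "0.1" = list(rheo_mult = 1.14,
                                           surv = c(1, 0.85, 0.64, 0.46)),
                              "1" = list(rheo_mult = 1.5,
                                         surv = c(0.5, 0.35, 0.24, 0.18))),
                            rheo_noise_sd = 0.05, seed = 1, path = NULL) {
  for (d in dose_effects)
    if (any(d$surv < 0 | d$surv > 1))
      stop("survival probabilities must lie in [0, 1]")
  df <- with_seed(derive_seed(seed, "ephys"), {
    rows <- list()
    for (cl in seq_len(n_cells)) {
      base_rheo <- round(stats::runif(1, baseline_rheobase_range[1],
                                      baseline_rheobase_range[2]) / 10) * 10
      rows[[length(rows) + 1L]] <- data.frame(
        cell = sprintf("cell_%02d", cl), dose = "baseline",
        rheobase_pA = base_rheo,
        aps_0.1Hz = .EPHYS_STIM[["0.1"]], aps_1Hz = .EPHYS_STIM[["1"]],
        aps_3Hz = .EPHYS_STIM[["3"]], aps_10Hz = .EPHYS_STIM[["10"]],
        check.names = FALSE, stringsAsFactors = FALSE)
      for (d in names(dose_effects)) {
        eff <- dose_effects[[d]]
        rheo <- base_rheo * eff$rheo_mult *
          exp(stats::rnorm(1, 0, rheo_noise_sd))
        aps <- vapply(seq_along(.EPHYS_FREQS), function(j)
          stats::rbinom(1, .EPHYS_STIM[[.EPHYS_FREQS[j]]], eff$surv[j]), 0L)
        rows[[length(rows) + 1L]] <- data.frame(
          cell = sprintf("cell_%02d", cl), dose = d,
          rheobase_pA = round(rheo),
          aps_0.1Hz = aps[1], aps_1Hz = aps[2], aps_3Hz = aps[3],
          aps_10Hz = aps[4], check.names = FALSE, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
  class(df) <- c("ephys_cells", "data.frame")
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}

#' Generate synthetic two-component current traces
#'
#' Builds a total sodium-current trace as a sum of components of the form
#' `a * (1 - exp(-t/tau_act)) * exp(-t/tau_inact)` (t measured from the step
#' onset) plus a baseline offset and optional Gaussian noise, alongside the
#' drug-resistant trace holding only the `slow` components. At
#' `noise_sd = 0`, [subtract_traces()] applied to the zero-subtracted pair
#' recovers the fast components exactly.
#'
#' @param components List of `list(amp =, tau_act =, tau_inact =)` (pA,
#'   seconds); default a fast-inactivating (1 ms) and a slow-inactivating
#'   (20 ms) inward component.
#' @param slow Indices of the components present in the resistant trace.
#' @param sample_rate Sampling rate in Hz (default 50000).
#' @param step_onset Step time in seconds (default 0.15, leaving a 0.14 s
#'   baseline window).
#' @param duration Record length in seconds.
#' @param baseline_offset Constant holding-current offset in pA.
#' @param noise_sd SD of additive Gaussian noise in pA.
#' @param capacitance Cell capacitance in pF.
#' @param seed Seed; NULL uses the current RNG stream.
#' @return A list with `total` and `slow` [current_trace()] objects.
#' @export
gen_traces <- function(components = list(
                         list(amp = -1500, tau_act = 1e-4, tau_inact = 1e-3),
                         list(amp = -600, tau_act = 3e-4, tau_inact = 20e-3)),
                       slow = 2L, sample_rate = 50000, step_onset = 0.15,
                       duration = 0.17, baseline_offset = 0, noise_sd = 0,
                       capacitance = 15, seed = NULL) {
  for (cp in components) stopifnot(cp$tau_act > 0, cp$tau_inact > 0)
  n <- floor(duration * sample_rate) + 1L
  tt <- (seq_len(n) - 1) / sample_rate
  rel <- tt - step_onset
  comp_signal <- function(cp) {
    s <- numeric(n)
    on <- rel >= 0
    s[on] <- cp$amp * (1 - exp(-rel[on] / cp$tau_act)) *
      exp(-rel[on] / cp$tau_inact)
    s
  }
  sig <- lapply(components, comp_signal)
  total <- Reduce(`+`, sig, numeric(n)) + baseline_offset
  slow <- intersect(slow, seq_along(components))
  slow_sig <- if (length(slow)) Reduce(`+`, sig[slow], numeric(n)) else numeric(n)
  slow_sig <- slow_sig + baseline_offset
  mk <- function(s) {
    if (noise_sd > 0) s <- s + stats::rnorm(n, 0, noise_sd)
    current_trace(s, sample_rate, step_onset, capacitance)
  }
  run <- function() list(total = mk(total), slow = mk(slow_sig))
  if (is.null(seed)) run() else with_seed(derive_seed(seed, "traces"), run())
}
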