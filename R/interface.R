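#' Read multi-model structural frames
#'
#' Reads a PDB-dialect coordinate file (fixed columns, `ATOM`/`HETATM`
#' records, frames delimited by `MODEL`/`ENDMDL`; a single-model file yields
#' one frame). Parsing is delegated to [bio3d::read.pdb()]; a pre-scan
#' rejects malformed coordinate records with the offending line number.
#' Hydrogens are retained and flagged in the `is_hydrogen` column.
#'
#' @param path Path to the coordinate file.
#' @return A list of class `frame_list`; each element is a data.frame of
#'   class `structure_frame` with columns `chain`, `resno`, `resid`, `elety`
#'   (atom name), `elesy` (element), `x`, `y`, `z`, `is_hydrogen`, and a
#'   `frame_index` attribute.
#' @export
read_frames <- function(path) {
  raw <- readLines(path, warn = FALSE)
  rec <- grep("^(ATOM  |HETATM)", raw)
  if (length(rec) == 0L) stop("no ATOM/HETATM records in ", path)
  for (ln in rec) {
    line <- raw[ln]
    if (nchar(line) < 54L)
      stop(sprintf("malformed coordinate record at line %d: too short", ln))
    xyz <- suppressWarnings(as.numeric(c(substr(line, 31, 38),
                                         substr(line, 39, 46),
                                         substr(line, 47, 54))))
    if (anyNA(xyz) || any(!is.finite(xyz)))
      stop(sprintf("malformed coordinate record at line %d: unparsable coordinates", ln))
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  at <- pdb$atom
  nfr <- nrow(pdb$xyz)
  if (is.null(nfr) || nfr < 1L) stop("zero frames parsed from ", path)
  elesy <- trimws(at$elesy)
  elety <- trimws(at$elety)
  ish <- toupper(elesy) %in% c("H", "D")
  noel <- is.na(elesy) | elesy == ""
  # name-based fallback when the element column is absent
  ish[noel] <- grepl("^[0-9]*[HD]", elety[noel])
  base <- data.frame(
    chain = as.character(at$chain), resno = as.integer(at$resno),
    resid = trimws(as.character(at$resid)), elety = elety, elesy = elesy,
    is_hydrogen = ish, stringsAsFactors = FALSE
  )
  key <- paste(base$chain, base$resno, base$elety)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue number, atom name) within a frame: ",
         key[duplicated(key)][1])
  frames <- lapply(seq_len(nfr), function(k) {
    co <- matrix(pdb$xyz[k, ], ncol = 3L, byrow = TRUE)
    fr <- base
    fr$x <- co[, 1]; fr$y <- co[, 2]; fr$z <- co[, 3]
    attr(fr, "frame_index") <- k
    class(fr) <- c("structure_frame", "data.frame")
    fr
  })
  structure(frames, class = "frame_list")
}

# Default partition of POPC atom names into head-group and acyl-tail atoms
# (choline + phosphate + glycerol backbone/ester = head; sn-1/sn-2 chain
# carbons = tail). The exact split is an assumption of the rule table, kept
# here so it is inspectable and serializable.
.POPC_HEAD_ATOMS <- c(
  "N", "C11", "C12", "C13", "C14", "C15",
  "P", "O11", "O12", "O13", "O14",
  "C1", "C2", "C3", "O21", "O22", "O31", "O32", "C21", "C31"
)

#' Atom-grouping rules for contact classification
#'
#' Rules assigning every atom of a frame to exactly one environment group:
#' `peptide` and `channel` are keyed by chain ID; `water`, `ion` and the
#' lipid groups by residue name, with lipid atoms split into `lipid_head`
#' versus `lipid_tail` by atom name; anything unmatched is `other`.
#'
#' @param peptide_chains Chain IDs holding peptide copies.
#' @param channel_chains Chain IDs holding channel subunits.
#' @param water_resnames Residue names treated as water.
#' @param lipid_resnames Residue names treated as lipid.
#' @param lipid_head_atoms Atom names (within lipid residues) assigned to the
#'   head group; remaining lipid atoms are tail.
#' @param ion_resnames Residue names treated as ions.
#' @return A list of class `group_rules`.
#' @export
group_rules <- function(peptide_chains = c("E", "F", "G", "H"),
                        channel_chains = c("A", "B", "C", "D"),
                        water_resnames = c("HOH", "TIP3", "TIP", "WAT", "SOL", "SPC"),
                        lipid_resnames = "POPC",
                        lipid_head_atoms = .POPC_HEAD_ATOMS,
                        ion_resnames = c("SOD", "CLA", "POT", "NA", "CL", "K")) {
  structure(list(peptide_chains = peptide_chains,
                 channel_chains = channel_chains,
                 water_resnames = water_resnames,
                 lipid_resnames = lipid_resnames,
                 lipid_head_atoms = lipid_head_atoms,
                 ion_resnames = ion_resnames),
            class = "group_rules")
}

#' @rdname group_rules
#' @param rules A `group_rules` object.
#' @param path File path for the YAML serialization.
#' @export
write_group_rules <- function(rules, path) {
  stopifnot(inherits(rules, "group_rules"))
  yaml::write_yaml(unclass(rules), path)
  invisible(path)
}

#' @rdname group_rules
#' @export
read_group_rules <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(group_rules, lapply(x, as.character))
}

#' Classify frame atoms into environment groups
#'
#' @param frame A `structure_frame`.
#' @param rules A [group_rules()] object.
#' @return A character vector (one entry per atom) over
#'   `{peptide, channel, lipid_head, lipid_tail, water, ion, other}`.
#' @export
classify_atoms <- function(frame, rules = group_rules()) {
  stopifnot(inherits(frame, "structure_frame"), inherits(rules, "group_rules"))
  if (!any(frame$chain %in% rules$peptide_chains))
    stop("no peptide chain (", paste(rules$peptide_chains, collapse = ","),
         ") present in frame")
  g <- rep("other", nrow(frame))
  is_lipid <- frame$resid %in% rules$lipid_resnames
  g[is_lipid] <- ifelse(frame$elety[is_lipid] %in% rules$lipid_head_atoms,
                        "lipid_head", "lipid_tail")
  g[frame$resid %in% rules$water_resnames] <- "water"
  g[frame$resid %in% rules$ion_resnames] <- "ion"
  g[frame$chain %in% rules$channel_chains] <- "channel"
  g[frame$chain %in% rules$peptide_chains] <- "peptide"
  g
}

#' Contact-analysis parameters
#'
#' @param cutoff Heavy-atom distance cutoff in Angstrom (default 3.5).
#' @param heavy_atoms_only Restrict the search to non-hydrogen atoms
#'   (default TRUE).
#' @param chain_pairs Interacting (channel, peptide) chain pairs as
#'   `"channel:peptide"` strings; default `A:E, B:F, C:G, D:H` for a
#'   four-fold channel with one peptide bound per voltage sensor.
#' @param method Distance-search backend passed to [pairs_within()].
#' @return A list of class `contact_params`.
#' @export
contact_params <- function(cutoff = 3.5, heavy_atoms_only = TRUE,
                           chain_pairs = c("A:E", "B:F", "C:G", "D:H"),
                           method = "cell") {
  stopifnot(cutoff > 0, length(chain_pairs) >= 1L)
  pr <- strsplit(chain_pairs, ":", fixed = TRUE)
  if (any(vapply(pr, length, 1L) != 2L))
    stop("chain_pairs must be 'channelChain:peptideChain' strings")
  structure(list(cutoff = cutoff, heavy_atoms_only = isTRUE(heavy_atoms_only),
                 channel_chain = vapply(pr, `[`, "", 1L),
                 peptide_chain = vapply(pr, `[`, "", 2L),
                 method = method),
            class = "contact_params")
}

#' Fractional residue-environment contacts across frames
#'
#' For every peptide residue position and environment group, the fraction of
#' (frame, chain-pair) observations in which any heavy atom of that residue
#' lies within the cutoff of any heavy atom of the group. The contact
#' indicator is binary per observation (an atom-pair count does not increase
#' it). For the `channel` group only atoms of the paired channel chain are
#' searched; membrane, water and ion atoms are shared across pairs but each
#' (frame, pair) still contributes one observation, so every group is
#' normalized by the same denominator `frames x pairs`.
#'
#' @param frames A `frame_list` from [read_frames()] (or a list of
#'   `structure_frame` objects).
#' @param rules A [group_rules()] object.
#' @param params A [contact_params()] object.
#' @return An object of class `contact_profile`: list with `values` (position
#'   x group matrix of exact count ratios), `counts`, `n_observations`,
#'   `cutoff`.
#' @export
fractional_contacts <- function(frames, rules = group_rules(),
                                params = contact_params()) {
  stopifnot(length(frames) >= 1L, inherits(params, "contact_params"))
  npairs <- length(params$channel_chain)
  if (npairs == 0L) stop("empty chain-pair list")
  f1 <- frames[[1]]
  miss <- setdiff(c(params$channel_chain, params$peptide_chain), unique(f1$chain))
  if (length(miss))
    stop("chain pair references chains absent from the frames: ",
         paste(miss, collapse = ","))
  groups <- c("lipid_head", "lipid_tail", "water", "ion", "channel")
  positions <- sort(unique(f1$resno[f1$chain %in% params$peptide_chain]))
  counts <- matrix(0L, nrow = length(positions), ncol = length(groups),
                   dimnames = list(positions, groups))
  for (fr in frames) {
    g <- classify_atoms(fr, rules)
    keep <- if (params$heavy_atoms_only) !fr$is_hydrogen else rep(TRUE, nrow(fr))
    co <- cbind(fr$x, fr$y, fr$z)
    env_idx <- lapply(c("lipid_head", "lipid_tail", "water", "ion"),
                      function(gr) which(g == gr & keep))
    names(env_idx) <- c("lipid_head", "lipid_tail", "water", "ion")
    for (p in seq_len(npairs)) {
      pch <- params$peptide_chain[p]
      cch <- params$channel_chain[p]
      chan_idx <- which(g == "channel" & fr$chain == cch & keep)
      for (ri in seq_along(positions)) {
        rmask <- which(fr$chain == pch & fr$resno == positions[ri] & keep)
        if (length(rmask) == 0L)
          stop(sprintf("residue %d of chain %s has zero heavy atoms",
                       positions[ri], pch))
        rxyz <- co[rmask, , drop = FALSE]
        for (gr in groups) {
          gi <- if (gr == "channel") chan_idx else env_idx[[gr]]
          if (length(gi) == 0L) next
          if (.any_within(rxyz, co[gi, , drop = FALSE], params$cutoff,
                          method = params$method))
            counts[ri, gr] <- counts[ri, gr] + 1L
        }
      }
    }
  }
  n_obs <- length(frames) * npairs
  structure(list(values = counts / n_obs, counts = counts,
                 n_observations = n_obs, cutoff = params$cutoff,
                 positions = positions),
            class = "contact_profile")
}

#' @export
print.contact_profile <- function(x, ...) {
  cat(sprintf("<contact_profile> %d positions x %d groups, %d observations, cutoff %.2f A\n",
              nrow(x$values), ncol(x$values), x$n_observations, x$cutoff))
  print(round(x$values, 3))
  invisible(x)
}

#' @export
as.data.frame.contact_profile <- function(x, ...) {
  data.frame(position = as.integer(rownames(x$values)),
             as.data.frame(x$values), row.names = NULL, check.names = FALSE)
}

#' Write a contact profile as CSV
#'
#' @param profile A `contact_profile`.
#' @param path Output path.
#' @export
write_contact_profile <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}

#' Build a contact profile from a position x group value table
#'
#' Convenience constructor used when contact fractions come from an external
#' table (e.g. a CSV written by [write_contact_profile()]) rather than from
#' frames.
#'
#' @param values Numeric matrix or data.frame, rows = positions (rownames or
#'   a `position` column), columns = groups.
#' @param n_observations Number of (frame, pair) observations behind the
#'   values.
#' @param cutoff Cutoff the values were computed with.
#' @return A `contact_profile`.
#' @export
contact_profile <- function(values, n_observations = NA_integer_, cutoff = 3.5) {
  if (is.data.frame(values) && "position" %in% names(values)) {
    rn <- values$position
    values <- as.matrix(values[setdiff(names(values), "position")])
    rownames(values) <- rn
  }
  values <- as.matrix(values)
  if (any(values < 0 | values > 1)) stop("contact fractions must lie in [0, 1]")
  structure(list(values = values, counts = NULL,
                 n_observations = n_observations, cutoff = cutoff,
                 positions = as.integer(rownames(values))),
            class = "contact_profile")
}

# Donor/acceptor and charged-atom tables for polar-interaction detection.
# Keyed by "RESID ATOM"; "* N"/"* O" cover the backbone of any amino acid.
.HB_DONORS <- c("* N", "ARG NE", "ARG NH1", "ARG NH2", "LYS NZ", "HIS ND1",
                "HIS NE2", "TRP NE1", "ASN ND2", "GLN NE2", "SER OG",
                "THR OG1", "TYR OH", "HOH O", "TIP3 OH2")
.HB_ACCEPTORS <- c("* O", "* OXT", "ASP OD1", "ASP OD2", "GLU OE1", "GLU OE2",
                   "ASN OD1", "GLN OE1", "SER OG", "THR OG1", "TYR OH",
                   "HIS ND1", "HIS NE2", "HOH O", "TIP3 OH2")
.SB_CATIONS <- c("ARG NE", "ARG NH1", "ARG NH2", "LYS NZ", "HIS ND1", "HIS NE2")
.SB_ANIONS <- c("ASP OD1", "ASP OD2", "GLU OE1", "GLU OE2", "* OXT")

.match_atom_table <- function(frame, table) {
  key <- paste(frame$resid, frame$elety)
  star <- paste("*", frame$elety)
  key %in% table | star %in% table
}

#' Detect polar interactions in a frame
#'
#' Geometric hydrogen-bond and salt-bridge detection. A hydrogen bond is a
#' donor/acceptor heavy-atom pair within the criterion distance (default
#' 3.5 Angstrom); when explicit hydrogens are present on the donor, the
#' donor-H...acceptor angle must additionally be at least `min_angle`
#' degrees. A salt bridge is a side-chain charged nitrogen/oxygen pair within
#' its criterion (default 4.0 Angstrom). Pairs within the same residue are
#' ignored.
#'
#' @param frame A `structure_frame`.
#' @param kind `"hbond"` or `"salt_bridge"`.
#' @param criteria Named list of criterion distances in Angstrom
#'   (`hbond`, `salt_bridge`) and `min_angle` in degrees.
#' @param interface_only If TRUE, keep only peptide-channel pairs.
#' @param rules [group_rules()] supplying the chain sets for
#'   `interface_only`.
#' @param method Distance-search backend.
#' @return A data.frame with one row per interaction (kind, both atom
#'   identities, distance), sorted by distance.
#' @export
find_polar_interactions <- function(frame, kind = c("hbond", "salt_bridge"),
                                    criteria = list(hbond = 3.5,
                                                    salt_bridge = 4.0,
                                                    min_angle = 120),
                                    interface_only = FALSE,
                                    rules = group_rules(),
                                    method = "cell") {
  kind <- match.arg(kind)
  stopifnot(inherits(frame, "structure_frame"))
  if (kind == "hbond") {
    di <- which(.match_atom_table(frame, .HB_DONORS) & !frame$is_hydrogen)
    ai <- which(.match_atom_table(frame, .HB_ACCEPTORS) & !frame$is_hydrogen)
    cut <- criteria$hbond
  } else {
    di <- which(.match_atom_table(frame, .SB_CATIONS) & !frame$is_hydrogen)
    ai <- which(.match_atom_table(frame, .SB_ANIONS) & !frame$is_hydrogen)
    cut <- criteria$salt_bridge
  }
  empty <- data.frame(kind = character(0), chain1 = character(0),
                      resno1 = integer(0), resid1 = character(0),
                      atom1 = character(0), chain2 = character(0),
                      resno2 = integer(0), resid2 = character(0),
                      atom2 = character(0), distance = numeric(0))
  if (length(di) == 0L || length(ai) == 0L) return(empty)
  co <- cbind(frame$x, frame$y, frame$z)
  pr <- pairs_within(co[di, , drop = FALSE], co[ai, , drop = FALSE], cut,
                     method = method)
  if (nrow(pr) == 0L) return(empty)
  i <- di[pr$i]; j <- ai[pr$j]
  keep <- !(frame$chain[i] == frame$chain[j] & frame$resno[i] == frame$resno[j])
  i <- i[keep]; j <- j[keep]; dd <- pr$dist[keep]
  if (kind == "hbond" && length(i) && any(frame$is_hydrogen)) {
    ok <- vapply(seq_along(i), function(k) {
      hs <- which(frame$is_hydrogen & frame$chain == frame$chain[i[k]] &
                    frame$resno == frame$resno[i[k]])
      if (length(hs) == 0L) return(TRUE)
      dh <- sqrt(.pair_dist2(co, co, rep(i[k], length(hs)), hs))
      hs <- hs[dh <= 1.3]  # hydrogens covalently bound to the donor
      if (length(hs) == 0L) return(TRUE)
      ang <- vapply(hs, function(h) {
        v1 <- co[i[k], ] - co[h, ]; v2 <- co[j[k], ] - co[h, ]
        acos(pmin(1, pmax(-1, sum(v1 * v2) /
                            sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      }, 0)
      any(ang >= criteria$min_angle)
    }, TRUE)
    i <- i[ok]; j <- j[ok]; dd <- dd[ok]
  }
  if (interface_only && length(i)) {
    pep <- rules$peptide_chains; chn <- rules$channel_chains
    ok <- (frame$chain[i] %in% pep & frame$chain[j] %in% chn) |
      (frame$chain[i] %in% chn & frame$chain[j] %in% pep)
    i <- i[ok]; j <- j[ok]; dd <- dd[ok]
  }
  out <- data.frame(kind = rep(kind, length(i)),
                    chain1 = frame$chain[i], resno1 = frame$resno[i],
                    resid1 = frame$resid[i], atom1 = frame$elety[i],
                    chain2 = frame$chain[j], resno2 = frame$resno[j],
                    resid2 = frame$resid[j], atom2 = frame$elety[j],
                    distance = dd, stringsAsFactors = FALSE)
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}
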