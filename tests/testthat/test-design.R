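test_that("scorefiles parse with validation of columns, tags and values", {
  txt <- gen_scorefile(n_designs = 50, seed = 5)
  ds <- read_scorefile(txt)
  expect_s3_class(ds, "design_set")
  expect_equal(nrow(ds$records), 50L)
  expect_true(all(nchar(ds$records$sequence) == 30L))
  expect_true(all(is.finite(ds$records$total_score)))

  hdr_only <- txt[1]
  expect_equal(nrow(read_scorefile(hdr_only)$records), 0L)

  bad <- txt
  bad[3] <- sub("^SCORE: [-0-9.]+", "SCORE: nan", bad[3])
  expect_error(read_scorefile(bad), "non-finite total_score.*line 3")

  dup <- c(txt[1:3], txt[3])
  expect_error(read_scorefile(dup), "duplicate design tag")

  expect_error(read_scorefile(sub("ddg", "dG_sep", txt[1])),
               "missing required column 'ddg'")
  # ... unless told where to look
  ds2 <- read_scorefile(c(sub("ddg", "dG_sep", txt[1]), txt[-1]),
                        ddg_col = "dG_sep")
  expect_equal(ds2$records$ddg, ds$records$ddg)

  expect_error(read_scorefile(c(txt, "SCORE: 1.0 extra_field")), "fields")
})

test_that("sequences can come from a companion FASTA keyed by tag", {
  txt <- gen_scorefile(n_designs = 5, seed = 6)
  ds <- read_scorefile(txt)
  tf <- withr::local_tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(seq_len(5), function(i)
    c(paste0(">", ds$records$tag[i]), ds$records$sequence[i]))), tf)
  # strip the sequence column, reattach from FASTA
  no_seq <- gsub(" [A-Z]{30} ", " ", txt)
  no_seq[1] <- sub(" sequence ", " ", no_seq[1])
  ds2 <- read_scorefile(no_seq, fasta = tf)
  expect_equal(ds2$records$sequence, ds$records$sequence)
})

test_that("selection cascade equals the brute-force double sort", {
  ds <- read_scorefile(gen_scorefile(n_designs = 1000, seed = 11))
  sel <- select_designs(ds, 100, 20)
  expect_equal(nrow(sel$records), 20L)
  oracle <- oracle_cascade(ds$records, 100, 20)
  expect_equal(sel$records$tag, oracle$tag)        # same set AND order
  expect_equal(sel$records$ddg, oracle$ddg)

  # idempotence
  expect_equal(select_designs(sel, 100, 20)$records, sel$records)

  # small sets are returned whole
  small <- read_scorefile(gen_scorefile(n_designs = 15, seed = 12))
  expect_equal(nrow(select_designs(small)$records), 15L)

  expect_error(select_designs(ds, 10, 20), "n_score >= n_ddg")
  expect_true(any(grepl("stage 2", sel$provenance)))
})

test_that("ties in the cascade break by tag lexicographic order", {
  recs <- data.frame(tag = c("d_b", "d_a", "d_c"),
                     total_score = c(-5, -5, -5), ddg = c(-1, -1, -2),
                     sequence = NA_character_, stringsAsFactors = FALSE)
  ds <- structure(list(records = recs, provenance = "synthetic"),
                  class = "design_set")
  sel <- select_designs(ds, 3, 2)
  expect_equal(sel$records$tag, c("d_c", "d_a"))
  expect_equal(oracle_cascade(recs, 3, 2)$tag, c("d_c", "d_a"))
})

test_that("PWM frequencies, information content and consensus behave", {
  same <- rep(strrep("ACDEF", 2), 20)
  p <- build_pwm(same)
  expect_true(all(abs(colSums(p$freq) - 1) < 1e-12))
  expect_true(all(apply(p$freq, 2, max) == 1))
  expect_equal(unname(p$information_content), rep(log2(20), 10))
  expect_equal(consensus(p), strrep("ACDEF", 2))

  # uniform first position carries zero information
  unif <- paste0(sort(c("A","C","D","E","F","G","H","I","K","L","M","N",
                        "P","Q","R","S","T","V","W","Y")), "AA")
  pu <- build_pwm(unif)
  expect_equal(unname(pu$information_content[1]), 0)
  expect_equal(unname(pu$information_content[2]), log2(20))
  expect_true(all(pu$information_content >= 0 &
                    pu$information_content <= log2(20)))

  # 50/50 tie resolves alphabetically
  pt <- build_pwm(c("CA", "AA"))
  expect_equal(substr(consensus(pt), 1, 1), "A")

  # a planted 70% majority residue is recovered as the consensus
  set.seed(31)
  aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  planted <- strsplit(strrep("KWRCE", 2), "")[[1]]
  seqs <- vapply(1:60, function(i) paste(vapply(planted, function(r) {
    if (runif(1) < 0.7) r else sample(setdiff(aa20, r), 1)
  }, ""), collapse = ""), "")
  expect_equal(consensus(build_pwm(seqs)), paste(planted, collapse = ""))

  expect_error(build_pwm(c("AA", "A")), "equal lengths")
  expect_error(build_pwm("AB1"), "outside the alphabet")
  # small-sample correction only lowers IC
  pc <- build_pwm(same, small_sample_correction = TRUE)
  expect_true(all(pc$information_content <= p$information_content))
})

test_that("the printed design resfile parses into the exact command partition", {
  spec <- parse_resfile(knotopt_file("protx2_design.resfile"))
  expect_equal(spec$default, list(command = "PIKAA",
                                  args = "ACDEFGHIKLMNPQRSTVWY"))
  expect_equal(nchar(spec$default$args), 20L)
  pos <- spec$positions
  expect_equal(nrow(pos), 14L)
  expect_true(all(pos$chain == "E"))
  expect_setequal(pos$resnum[pos$command == "NATAA"], c(5, 6, 22, 24, 27, 29))
  pik <- pos[pos$command == "PIKAA", ]
  expect_equal(pik$args[order(pik$resnum)], c("R", "E", "L"))
  expect_equal(sort(pik$resnum), c(20, 28, 30))
  not <- pos[pos$command == "NOTAA", ]
  expect_setequal(not$resnum, c(1, 4, 7, 8, 13))
  expect_true(all(not$args == "ED"))

  # write-parse identity
  expect_identical(parse_resfile(write_resfile(spec)), spec)
})

test_that("resfile parsing rejects malformed input", {
  expect_error(parse_resfile(c("PIKAA A", "no start here")), "start")
  expect_error(parse_resfile(c("5 E NATAA", "start")), "body line before")
  expect_error(parse_resfile(c("FIXME A", "start")), "unknown command")
  expect_error(parse_resfile(c("start", "5 E WIBBLE")), "unknown command")
  empty <- parse_resfile(c("NATAA", "start"))
  expect_equal(nrow(empty$positions), 0L)
  expect_equal(empty$default$command, "NATAA")
})

test_that("random resfile specs round-trip through text", {
  set.seed(41)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  for (k in 1:15) {
    n <- sample(1:8, 1)
    pos <- sort(sample(1:30, n))
    cmd <- sample(c("PIKAA", "NATAA", "NOTAA"), n, replace = TRUE)
    args <- vapply(seq_len(n), function(i) {
      if (cmd[i] == "NATAA") "" else
        paste(sample(aa, sample(1:4, 1)), collapse = "")
    }, "")
    spec <- resfile_spec(
      default = list(command = "PIKAA",
                     args = paste(sample(aa, 10), collapse = "")),
      positions = data.frame(resnum = pos, chain = "E", command = cmd,
                             args = args, stringsAsFactors = FALSE))
    expect_identical(parse_resfile(write_resfile(spec)), spec)
  }
})

test_that("constraints derived from a contact profile reproduce the printed partition", {
  vals <- matrix(0, nrow = 30, ncol = 4,
                 dimnames = list(1:30, c("lipid_head", "lipid_tail",
                                         "water", "channel")))
  vals[c(1, 4, 7, 8, 13), "lipid_head"] <- 0.5
  vals[c(1, 4, 7, 8, 13), "lipid_tail"] <- 0.4
  prof <- contact_profile(vals)
  spec <- derive_constraints(
    prof,
    fixed_nataa = c(5, 6, 22, 24, 27, 29),
    fixed_identity = c("20" = "R", "28" = "E", "30" = "L"),
    lipid_threshold = 0.25,
    scaffold_cys = integer(0))
  printed <- parse_resfile(knotopt_file("protx2_design.resfile"))
  key <- function(s) {
    p <- s$positions[order(s$positions$resnum, s$positions$command), ]
    rownames(p) <- NULL
    p
  }
  expect_equal(key(spec), key(printed))
  expect_equal(spec$default, printed$default)

  expect_error(derive_constraints(prof, lipid_threshold = 1.01), "\\(0, 1\\]")
  expect_error(derive_constraints(prof, fixed_nataa = 20,
                                  fixed_identity = c("20" = "R")),
               "conflicting")

  # all-zero profile: only the scaffold cysteines receive commands
  zero <- derive_constraints(contact_profile(vals * 0))
  expect_equal(zero$positions$resnum, c(2, 9, 15, 16, 21, 25))
  expect_true(all(zero$positions$command == "NATAA"))
})

test_that("cascade plus consensus recovers a planted design motif", {
  txt <- gen_scorefile(n_designs = 400, seed = 21,
                       planted_motif = c("20" = "R", "28" = "E"),
                       enrichment = 0.9, n_score = 100, n_ddg = 20)
  sel <- select_designs(read_scorefile(txt), 100, 20)
  cons <- consensus(build_pwm(sel$records$sequence))
  expect_equal(substr(cons, 20, 20), "R")
  expect_equal(substr(cons, 28, 28), "E")
})
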