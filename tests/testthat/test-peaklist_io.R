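test_that("Sparky lists parse assignments, shifts and dialect variants", {
  f <- withr::local_tempfile(fileext = ".list")
  writeLines(c("      Assignment        w1       w2",
               "D99N-H 115.20 8.41",
               "E66N-H 120.10 7.95"), f)
  st <- read_sparky_list(f, condition(0, 0.1))
  expect_s3_class(st, "shift_table")
  expect_setequal(st$peaks$residue_number, c(99, 66))
  expect_setequal(st$peaks$residue_code, c("D", "E"))
  expect_equal(st$peaks$shift_N[st$peaks$residue_number == 99], 115.20)
  expect_equal(st$peaks$shift_H[st$peaks$residue_number == 99], 8.41)

  # suffix dialects: bare residue, NH, N-HN all carry the same number
  writeLines(c("D99 115.20 8.41", "E66NH 120.10 7.95",
               "K15N-HN 121.5 8.1"), f)
  st2 <- read_sparky_list(f, condition(0, 0.1))
  expect_setequal(st2$peaks$residue_number, c(99, 66, 15))

  # swapped-axis dialect
  writeLines("D99N-H 8.41 115.20", f)
  st3 <- read_sparky_list(f, condition(0, 0.1), axis_order = "H-N")
  expect_equal(st3$peaks$shift_N, 115.20)
  expect_equal(st3$peaks$shift_H, 8.41)
})

test_that("Sparky parser handles empty files and rejects bad lines", {
  f <- withr::local_tempfile(fileext = ".list")
  writeLines("      Assignment        w1       w2", f)
  expect_equal(nrow(read_sparky_list(f, condition(0, 0.1))$peaks), 0)

  writeLines(c("D99N-H 115.20 8.41", "D99N-H abc 8.41"), f)
  expect_error(read_sparky_list(f, condition(0, 0.1)), "line 2.*non-numeric")

  writeLines("??? 115.20 8.41", f)
  expect_error(read_sparky_list(f, condition(0, 0.1)), "unparsable")

  writeLines(c("D99N-H 115.20 8.41", "D99N-H 115.30 8.42"), f)
  expect_error(read_sparky_list(f, condition(0, 0.1)), "duplicate residue 99")

  writeLines("D99N-H 115.20", f)
  expect_error(read_sparky_list(f, condition(0, 0.1)), ">= 3 fields")

  expect_error(read_sparky_list(file.path(tempdir(), "nope.list"),
                                condition(0, 0.1)), "not found")
})

test_that("Sparky write/read round trip is the identity to 4 decimals", {
  set.seed(11)
  f <- withr::local_tempfile(fileext = ".list")
  for (rep in 1:5) {
    n <- sample(3:30, 1)
    st <- shift_table(sample(1:127, n),
                      sample(setdiff(LETTERS[1:20], c("B", "J", "O", "P")),
                             n, replace = TRUE),
                      runif(n, 105, 130), runif(n, 6.5, 10),
                      condition(runif(1, 0, 100), 0.1))
    write_sparky_list(st, f)
    back <- read_sparky_list(f, st$condition)
    expect_equal(back$peaks$residue_number, st$peaks$residue_number)
    expect_equal(back$peaks$shift_N, st$peaks$shift_N, tolerance = 1e-4)
    expect_equal(back$peaks$shift_H, st$peaks$shift_H, tolerance = 1e-4)
  }
})

test_that("shift tables enforce amide-panel invariants", {
  expect_error(shift_table(c(5, 5), c("A", "A"), c(120, 121), c(8, 8.1),
                           condition(0, 0.1)), "duplicate")
  expect_warning(st <- shift_table(c(5, 6), c("A", "P"), c(120, 121),
                                   c(8, 8.1), condition(0, 0.1)),
                 "proline")
  expect_equal(st$peaks$residue_number, 5)   # proline dropped
  expect_warning(shift_table(5, "A", 150, 8, condition(0, 0.1)),
                 "amide window")
  # retained despite the warning
  st2 <- suppressWarnings(shift_table(5, "A", 150, 8, condition(0, 0.1)))
  expect_equal(st2$peaks$shift_N, 150)
  expect_error(condition(-1, 0.1), "non-negative")
})

test_that("shift CSVs split by ligand concentration in ascending order", {
  f <- withr::local_tempfile(fileext = ".csv")
  d <- data.frame(residue_number = c(99, 66, 99, 66),
                  residue_code = c("D", "E", "D", "E"),
                  shift_N = c(115.2, 120.1, 115.3, 120.2),
                  shift_H = c(8.41, 7.95, 8.44, 7.98),
                  ligand_conc = c(10, 10, 0, 0))   # deliberately unordered
  write.csv(d, f, row.names = FALSE)
  tabs <- read_shift_csv(f, protein_conc_monomer = 0.1)
  expect_length(tabs, 2)
  expect_equal(vapply(tabs, function(t) t$condition$ligand_conc,
                      numeric(1)), c(0, 10))
  expect_equal(nrow(tabs[[1]]$peaks), 2)

  d$shift_H <- NULL
  write.csv(d, f, row.names = FALSE)
  expect_error(read_shift_csv(f), "shift_H")

  d2 <- rbind(data.frame(residue_number = 99, residue_code = "D",
                         shift_N = 115.2, shift_H = 8.41, ligand_conc = 0),
              data.frame(residue_number = 99, residue_code = "D",
                         shift_N = 115.2, shift_H = 8.41, ligand_conc = 0))
  write.csv(d2, f, row.names = FALSE)
  expect_error(read_shift_csv(f), "duplicated")
})

test_that("CSP tables round-trip through TSV to 6 decimals", {
  tabs <- make_pair_tables(c(10, 20, 30), c(8, 8.2, 8.4),
                           c(110, 115, 120),
                           c(0.031234567, -0.01, 0),
                           c(0.131234567, 0.05, -0.2))
  prof <- build_profile(tabs)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_csp_table(prof, f)
  lines <- readLines(f)
  expect_length(lines, 1 + 3 * 2)     # header + residues x points
  back <- read_csp_table(f)
  expect_equal(back$residues, prof$residues)
  expect_lt(max(abs(back$delta_combined - prof$delta_combined)), 1e-6)
  expect_lt(max(abs(back$delta_H - prof$delta_H)), 1e-6)
  expect_equal(back$tracked, prof$tracked, ignore_attr = TRUE)
})

test_that("untracked cells are written with empty shifts and tracked=false", {
  tabs <- make_pair_tables(c(10, 20), c(8, 8.2), c(110, 115),
                           c(0.03, 0.01), c(0.1, 0.1))
  tabs[[2]] <- shift_table(10, "A", 110.1, 8.03, tabs[[2]]$condition)
  prof <- build_profile(tabs)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_csp_table(prof, f)
  row20 <- grep("^20\\t100", readLines(f), value = TRUE)
  expect_match(row20, "\\t\\t\\t\\tfalse$")
  expect_error(write_csp_table(prof, file.path(tempdir(), "no/such/dir/x.tsv")),
               "cannot write")
})
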