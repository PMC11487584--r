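test_that("the composition grammar parses layers and mixed layers", {
  c1 <- parseComposition("ST+CB+CSF+NB")
  expect_length(c1@layers, 4L)
  expect_identical(c1@layers[[3L]], "CSF")
  c2 <- parseComposition("SST+CB+CSF/NB")
  expect_length(c2@layers, 3L)
  expect_setequal(c2@layers[[3L]], c("CSF", "NB"))
  expect_error(parseComposition("ST+XX+NB"), "XX")
  expect_error(parseComposition("ST++NB"), "empty layer")
  expect_error(parseComposition(""), "non-empty")
  expect_error(parseComposition("ST+CB/A/NB"), "exactly 2")
  # whitespace normalizes away
  expect_identical(formatComposition(parseComposition(" ST + CB + NB ")),
                   "ST+CB+NB")
})

test_that("every printed composition category round-trips through the grammar", {
  fix <- compositionFixture()
  expect_identical(nrow(fix), 32L)
  for (s in fix$composition)
    expect_identical(formatComposition(parseComposition(s)), s)
  # categorized ROI counts sum to the total minus the three omitted for
  # missing CT
  expect_identical(sum(fix$count), 121L - 3L)
  expect_identical(fix$count[fix$composition == "ST+CB+CSF+NB"], 22L)
})

test_that("ROI area follows the circular model", {
  expect_equal(roiArea(15), pi * 225)
  expect_equal(round(roiArea(15), -2), 700)
  expect_identical(roiArea(0), 0)
  expect_error(roiArea(-1), "nonnegative")
})

test_that("the long table holds exactly two ordered rows per ROI", {
  rois <- cohortFixture()
  tab <- toLongTable(rois)
  expect_identical(nrow(tab), 2L * nrow(rois))
  expect_identical(nrow(tab), 242L)
  expect_true(all(table(tab$measurement_id) == 2L))
  # deterministic order: measurement id, then wavelength ascending
  expect_identical(tab$wavelength_nm, rep(c(687, 830), nrow(rois)))
  expect_true(!is.unsorted(tab$measurement_id))
  # StO2/BFI repeat across a ROI pair
  expect_identical(tab$sto2_percent[seq(1, nrow(tab), 2)],
                   tab$sto2_percent[seq(2, nrow(tab), 2)])
  one <- rois[1L, , drop = FALSE]
  expect_identical(nrow(toLongTable(one)), 2L)
  dup <- rbind(rois[1:2, ], rois[1L, ])
  err <- tryCatch(toLongTable(dup), error = function(e) e)
  expect_s3_class(err, "diffuseQC_schema_error")
})

test_that("cohort summaries reproduce the printed proportions", {
  tab <- toLongTable(cohortFixture())
  s <- summarizeDataset(tab)
  expect_identical(s$n_rois, 121L)
  expect_identical(s$n_rows, 242L)
  expect_identical(s$n_subjects, 36L)
  fl <- s$flags
  expect_identical(fl$yes[fl$flag == "surgery"], 23L)
  expect_identical(fl$no[fl$flag == "surgery"], 98L)
  expect_equal(fl$percent_yes[fl$flag == "surgery"], 19)
  expect_identical(fl$yes[fl$flag == "skull"], 108L)
  expect_equal(fl$percent_yes[fl$flag == "skull"], 89)
  expect_equal(unname(s$cohorts[c("MCA", "TBI", "SAH")]), c(9L, 26L, 1L))
  expect_equal(unname(s$gender[c("M", "F")]), c(27L, 9L))
  expect_equal(round(s$age_mean), 41)
  expect_equal(round(s$age_sd), 15)
  expect_identical(sum(s$compositions), 118L)
  expect_identical(unname(s$compositions["ST+CB+CSF+NB"]), 22L)
  # a single-ROI table with surgery gives 100%
  one <- toLongTable(cohortFixture()[5, , drop = FALSE])
  one$surgery <- TRUE
  s1 <- summarizeDataset(one)
  expect_equal(s1$flags$percent_yes[s1$flags$flag == "surgery"], 100)
  expect_error(summarizeDataset(tab[0, ]), "empty")
})

test_that("summaries are invariant to row order and table IO round-trips", {
  tab <- toLongTable(cohortFixture())
  set.seed(1)
  shuffled <- tab[sample(nrow(tab)), ]
  a <- summarizeDataset(tab)
  b <- summarizeDataset(shuffled)
  expect_equal(a$flags, b$flags)
  expect_equal(sort(a$compositions), sort(b$compositions))
  expect_equal(a$age_mean, b$age_mean)
  path <- file.path(tempdir(), "cohort_long.csv")
  writeDatasetCSV(tab, path)
  back <- readDatasetCSV(path)
  expect_identical(nrow(back), nrow(tab))
  expect_equal(back$mua_percm, tab$mua_percm)
  bad <- tab[, setdiff(names(tab), "wavelength_nm")]
  path2 <- file.path(tempdir(), "bad.csv")
  write.csv(bad, path2, row.names = FALSE)
  err <- tryCatch(readDatasetCSV(path2), error = function(e) e)
  expect_s3_class(err, "diffuseQC_schema_error")
})
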