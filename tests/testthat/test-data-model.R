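# Containers, alignment rules and delimited-file round trips.

make_clin <- function(ids, age = seq_along(ids) + 40) {
  data.frame(patient_id = ids,
             cancer_type = rep_len(c("A", "B"), length(ids)),
             gender = rep_len(c("female", "male"), length(ids)),
             race = rep_len(c("x", "y"), length(ids)),
             histological_type = rep_len(c("h1", "h2"), length(ids)),
             age = age, stringsAsFactors = FALSE)
}

test_that("availability is derived from zero rows and re-derivable", {
  ids <- c("p1", "p2", "p3")
  X <- matrix(c(1, 2, 0, 3, 4, 0), 3, 2, byrow = TRUE,
              dimnames = list(ids, c("g1", "g2")))
  X[3, ] <- 0
  ds <- multimodal_dataset(
    clinical = make_clin(ids),
    omics = list(mRNA = X),
    survival = data.frame(patient_id = ids, time = 1:3, event = c(1, 0, 1))
  )
  expect_equal(unname(ds$availability[, "mRNA"]), c(1, 1, 0))
  expect_true(all(ds$omics$mRNA[3, ] == 0))
  # mask is authoritative: declaring a patient unavailable zeroes the row
  av <- ds$availability; av["p2", "mRNA"] <- 0
  ds2 <- multimodal_dataset(
    clinical = make_clin(ids), omics = list(mRNA = X),
    survival = ds$survival, availability = av)
  expect_true(all(ds2$omics$mRNA[2, ] == 0))
})

test_that("reading files joins inner on clinical/survival, outer on omics", {
  dir <- withr::local_tempdir()
  write.table(make_clin(c("p1", "p2", "p3")),
              file.path(dir, "clin.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(patient_id = c("p1", "p2", "p3", "p4"),
                         time = c(5, 6, 7, 8), event = c(1, 0, 1, 1)),
              file.path(dir, "surv.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  # only 2 of 3 patients have mRNA
  write.table(data.frame(patient_id = c("p1", "p2"), g1 = c(1, 2),
                         g2 = c(3, 4)),
              file.path(dir, "mrna.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_message(
    ds <- read_dataset(file.path(dir, "clin.tsv"),
                       c(mRNA = file.path(dir, "mrna.tsv")),
                       file.path(dir, "surv.tsv")),
    "dropped 1 patient")
  expect_equal(ds$patient_ids, c("p1", "p2", "p3"))
  expect_equal(unname(ds$availability[, "mRNA"]), c(1, 1, 0))
  expect_true(all(ds$omics$mRNA["p3", ] == 0))

  # header-only omics file: every patient unavailable
  writeLines("patient_id\tg1", file.path(dir, "empty.tsv"))
  ds2 <- read_dataset(file.path(dir, "clin.tsv"),
                      c(mRNA = file.path(dir, "empty.tsv")),
                      file.path(dir, "surv.tsv"))
  expect_true(all(ds2$availability[, "mRNA"] == 0))
})

test_that("duplicate IDs and non-numeric omics cells are hard errors", {
  dir <- withr::local_tempdir()
  clin <- make_clin(c("p1", "p1", "p2"))
  write.table(clin, file.path(dir, "clin.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  surv <- data.frame(patient_id = c("p1", "p2"), time = 1:2, event = c(1, 1))
  write.table(surv, file.path(dir, "surv.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_dataset(file.path(dir, "clin.tsv"), c(),
                            file.path(dir, "surv.tsv")),
               "duplicate patient IDs")

  write.table(make_clin(c("p1", "p2")), file.path(dir, "clin2.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(patient_id = c("p1", "p2"), g1 = c("1.5", "oops")),
              file.path(dir, "bad.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_dataset(file.path(dir, "clin2.tsv"),
                            c(mRNA = file.path(dir, "bad.tsv")),
                            file.path(dir, "surv.tsv")),
               "non-numeric value.*row 2.*g1")
})

test_that("write/read round trip is bit-exact and preserves alignment", {
  fx <- tiny_fixture()
  ds <- fx$data
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir)
  expect_true(all(file.exists(paths)))
  ds2 <- read_dataset_dir(dir)
  expect_identical(ds2$omics, ds$omics)
  expect_identical(ds2$availability, ds$availability)
  expect_identical(ds2$survival, ds$survival)
  expect_identical(ds2$clinical, ds$clinical)
  # alignment invariant: every component reports the same patient order
  expect_identical(rownames(ds2$availability), ds2$patient_ids)
  for (mod in names(ds2$omics)) {
    expect_identical(rownames(ds2$omics[[mod]]), ds2$patient_ids)
  }
  expect_identical(ds2$survival$patient_id, ds2$patient_ids)
})

test_that("an empty (0-patient) dataset writes valid header-only files", {
  ids <- character(0)
  ds <- multimodal_dataset(
    clinical = make_clin(ids),
    omics = list(mRNA = matrix(0, 0, 2, dimnames = list(NULL, c("g1", "g2")))),
    survival = data.frame(patient_id = ids, time = numeric(0),
                          event = numeric(0))
  )
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir)
  expect_true(all(file.exists(paths)))
  expect_equal(length(readLines(paths["clinical"])), 1L)
  expect_equal(length(readLines(paths["mRNA"])), 1L)
})

test_that("dataset subsetting keeps components aligned", {
  ds <- tiny_fixture()$data
  sub <- ds[c(3, 5, 8)]
  expect_equal(n_patients(sub), 3L)
  expect_identical(sub$patient_ids, ds$patient_ids[c(3, 5, 8)])
  expect_identical(sub$omics$mRNA, ds$omics$mRNA[c(3, 5, 8), ])
  expect_identical(unname(sub$availability),
                   unname(ds$availability[c(3, 5, 8), ]))
})
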