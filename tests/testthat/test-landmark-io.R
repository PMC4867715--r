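test_that("TPS records parse with scale, preserve order, and round-trip", {
  tmp <- withr::local_tempfile(fileext = ".tps")
  set.seed(3)
  shapes <- lapply(1:3, function(i) round(rand_shape(15) * 100, 4))
  txt <- unlist(lapply(1:3, function(i)
    c("LM=15",
      apply(shapes[[i]], 1, function(p) paste(p, collapse = " ")),
      sprintf("ID=spec%d", i), "SCALE=0.01")))
  writeLines(txt, tmp)
  configs <- read_tps(tmp, tooth = "M1")
  expect_length(configs, 3)
  expect_identical(vapply(configs, `[[`, character(1), "id"),
                   c("spec1", "spec2", "spec3"))
  expect_equal(configs[[2]]$landmarks, shapes[[2]], ignore_attr = TRUE)
  expect_equal(configs[[1]]$scale, 0.01)

  out <- withr::local_tempfile(fileext = ".tps")
  write_tps(configs, out)
  back <- read_tps(out, tooth = "M1")
  for (i in 1:3)
    expect_equal(back[[i]]$landmarks, configs[[i]]$landmarks,
                 tolerance = 1e-10)
})

test_that("malformed TPS records raise errors naming the record", {
  tmp <- withr::local_tempfile(fileext = ".tps")
  sh <- round(rand_shape(15, seed = 4), 3)
  writeLines(c("LM=15", apply(sh, 1, paste, collapse = " ")[1:14], "ID=a"),
             tmp)
  expect_error(read_tps(tmp, "M1"), "14 coordinate lines")

  writeLines(c("LM=14", apply(sh[1:14, ], 1, paste, collapse = " "),
               "ID=a", "SCALE=1"), tmp)
  expect_error(read_tps(tmp, "M1"), "LM=14")

  bad <- apply(sh, 1, paste, collapse = " ")
  bad[7] <- "1.0 oops"
  writeLines(c("LM=15", bad, "ID=a", "SCALE=1"), tmp)
  expect_error(read_tps(tmp, "M1"), "landmark line 7")

  writeLines(character(0), tmp)
  expect_error(read_tps(tmp, "M1"), "empty")
})

test_that("a missing SCALE line defaults to 1 with a warning", {
  tmp <- withr::local_tempfile(fileext = ".tps")
  sh <- round(rand_shape(15, seed = 5), 3)
  writeLines(c("LM=15", apply(sh, 1, paste, collapse = " "), "ID=x"), tmp)
  expect_warning(configs <- read_tps(tmp, "M1"), "assuming scale 1")
  expect_equal(configs[[1]]$scale, 1)
})

test_that("coordinate-table CSV round-trips configurations", {
  set.seed(6)
  configs <- lapply(1:4, function(i)
    landmark_config(rand_shape(15), id = paste0("s", i), tooth = "M2",
                    side = if (i %% 2) "left" else "right", scale = 0.02,
                    fossil = i == 4))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_landmark_csv(configs, tmp)
  back <- read_landmark_csv(tmp)
  expect_length(back, 4)
  for (i in 1:4) {
    expect_equal(back[[i]]$landmarks, configs[[i]]$landmarks,
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_identical(back[[i]]$side, configs[[i]]$side)
    expect_identical(back[[i]]$fossil, configs[[i]]$fossil)
  }
})

test_that("configuration validation enforces the landmark invariants", {
  sh <- rand_shape(15, seed = 7)
  expect_error(landmark_config(sh[1:14, ], "a", "M1"), "14 landmarks")
  sh2 <- sh; sh2[3, ] <- sh2[9, ]
  expect_error(landmark_config(sh2, "a", "M1"), "coincident")
  expect_error(landmark_config(sh, "a", "M1", scale = -1), "positive")
  sh3 <- sh; sh3[1, 1] <- NA
  expect_error(landmark_config(sh3, "a", "M1"), "non-finite")
})

test_that("scale application is linear and idempotent by contract", {
  cf <- landmark_config(rand_shape(15, seed = 8), "a", "M1", scale = 0.5)
  scaled <- apply_scale(cf)
  expect_equal(scaled$landmarks, cf$landmarks * 0.5)
  expect_equal(scaled$scale, 1)
  expect_equal(apply_scale(scaled)$landmarks, scaled$landmarks)

  cf1 <- landmark_config(rand_shape(15, seed = 9), "a", "M1", scale = 1)
  expect_equal(apply_scale(cf1)$landmarks, cf1$landmarks)
})

test_that("side standardization is an involution and commutes with scaling", {
  right <- landmark_config(rand_shape(15, seed = 10), "r", "M1",
                           side = "right")
  expect_identical(standardize_side(right), right)

  # synthesize the left antimere: inverse of the standardization map
  lm <- right$landmarks[mirror_pairs(), ]
  lm[, 2] <- -lm[, 2]
  lm <- sweep(lm, 2, apply(lm, 2, min))
  left <- landmark_config(lm, "l", "M1", side = "left")
  std <- standardize_side(left)
  expect_identical(std$side, "right")
  shift <- function(x) sweep(x, 2, apply(x, 2, min))
  expect_lt(max(abs(shift(std$landmarks) - shift(right$landmarks))), 1e-12)

  # mirroring brings the left antimere's shape onto the right template
  d_before <- procrustes_distance(left$landmarks, right$landmarks)
  d_after <- procrustes_distance(std$landmarks, right$landmarks)
  expect_same_shape(std$landmarks, right$landmarks, tol = 1e-12)
  expect_gt(d_before, d_after)

  # scaling commutes with mirroring
  left_s <- landmark_config(lm, "l", "M1", side = "left", scale = 0.3)
  a <- apply_scale(standardize_side(left_s))$landmarks
  b <- standardize_side(apply_scale(left_s))$landmarks
  expect_equal(shift(a), shift(b), tolerance = 1e-12)
})

test_that("dataset assembly validates ids, taxonomy coverage and teeth", {
  set.seed(11)
  configs <- lapply(1:3, function(i)
    landmark_config(rand_shape(15), paste0("e", i), "M1"))
  fossil <- landmark_config(rand_shape(15), "F1", "M1", fossil = TRUE)
  tax <- toy_taxonomy(paste0("e", 1:3))
  ds <- shape_dataset(c(configs, list(fossil)), tax)
  expect_s3_class(ds, "shape_dataset")
  expect_equal(nrow(ds$info), 4)
  expect_equal(sum(ds$info$fossil), 1)

  expect_error(shape_dataset(configs, toy_taxonomy(c("e1", "e2"))), "e3")
  dup <- c(configs, list(landmark_config(rand_shape(15), "e1", "M1")))
  expect_error(shape_dataset(dup, tax), "duplicate")
  mixed <- c(configs, list(landmark_config(rand_shape(15), "m", "M2")))
  expect_error(shape_dataset(mixed, tax), "mixed teeth")
})

test_that("taxonomy validation rejects labels outside the two schemes", {
  tax <- toy_taxonomy("e1")
  bad <- tax; bad$subfamily_G <- "Madeupinae"
  expect_error(platymorph:::validate_taxonomy(bad), "subfamily_G")
  bad <- tax; bad$family <- "Hominidae"
  expect_error(platymorph:::validate_taxonomy(bad), "family")
  # the genus map honours the two schemes' disagreements
  pt <- platyrrhine_taxonomy()
  expect_identical(unique(pt$subfamily_R[pt$genus == "Saimiri"]), "Cebinae")
  expect_identical(unique(pt$subfamily_G[pt$genus == "Saimiri"]),
                   "Saimiriinae")
  expect_setequal(unique(pt$genus[pt$subfamily_R == "Homunculinae"]),
                  c("Aotus", "Callicebus"))
})
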