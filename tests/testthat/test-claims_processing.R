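test_that("endometriosis codes are recognized by root, dot- and case-insensitively", {
  expect_true(is_endometriosis_code("617.1", "ICD9"))
  expect_true(is_endometriosis_code("N80.3", "ICD10"))
  expect_true(is_endometriosis_code("n803", "ICD10"))
  expect_true(is_endometriosis_code("6171", "ICD9"))
  expect_true(is_endometriosis_code("617", "ICD9"))
  expect_true(is_endometriosis_code("N80", "ICD10"))
  expect_false(is_endometriosis_code("616.1", "ICD9"))
  expect_false(is_endometriosis_code("N81.0", "ICD10"))
  expect_false(is_endometriosis_code("625.9", "ICD9"))
  # root must belong to the declared system
  expect_false(is_endometriosis_code("617.1", "ICD10"))
  expect_false(is_endometriosis_code("N80.1", "ICD9"))
})

test_that("code-to-subtype mapping uses longest prefix and NOS fallback", {
  expect_equal(format(map_code_to_subtype("617.1")), "OE")
  expect_equal(format(map_code_to_subtype("N801")), "OE")
  expect_equal(format(map_code_to_subtype("617.3")), "SE")
  expect_equal(format(map_code_to_subtype("N80.4")), "DE")
  expect_true(map_code_to_subtype("N80.9")$nos_only)
  expect_true(map_code_to_subtype("617.2")$nos_only)
  # any code under an empty map is NOS
  expect_true(map_code_to_subtype("617.1", list())$nos_only)
  # longest prefix wins over a shorter one
  m <- list("617" = "SE", "617.1" = "OE")
  expect_equal(format(map_code_to_subtype("617.1", m)), "OE")
  expect_equal(format(map_code_to_subtype("617.9", m)), "SE")
  expect_error(map_code_to_subtype("625.9"), "not an endometriosis")
})

test_that("window filter keeps surgery+30, drops surgery+31, and is idempotent", {
  cfg <- run_config(window_days = 30L)
  sdates <- c(A = as.Date("2008-06-01"))
  mk <- function(offsets) {
    new_claims <- data.frame(
      participant_id = "A", code_system = "ICD9", code = "617.9",
      service_date = as.Date("2008-06-01") + offsets, source = "ehr",
      stringsAsFactors = FALSE)
    structure(new_claims, class = c("claims_table", "data.frame"))
  }
  claims <- mk(c(-10, 0, 30, 31, 90))
  kept <- filter_claims_window(claims, sdates, cfg)
  expect_equal(as.integer(kept$service_date - sdates[["A"]]), c(-10, 0, 30))
  expect_identical(filter_claims_window(kept, sdates, cfg), kept)
  # claims outside the study period are removed even if inside the window
  early <- mk(0)
  early$service_date <- as.Date("2006-12-15")
  expect_identical(nrow(filter_claims_window(early, sdates, cfg)), 0L)
  # empty input passes through
  empty <- mk(0)[0, ]
  expect_identical(nrow(filter_claims_window(empty, sdates, cfg)), 0L)
})

test_that("test labels aggregate retained codes per participant", {
  cfg <- run_config()
  sdates <- c(A = as.Date("2008-06-01"), B = as.Date("2008-06-01"),
              C = as.Date("2008-06-01"), D = as.Date("2008-06-01"))
  claims <- structure(data.frame(
    participant_id = c("A", "B", "B", "C"),
    code_system = c("ICD9", "ICD10", "ICD10", "ICD9"),
    code = c("617.9", "N80.1", "N80.4", "617.3"),
    service_date = as.Date("2008-06-01") + c(5, 5, 10, 40),
    source = "ehr", stringsAsFactors = FALSE),
    class = c("claims_table", "data.frame"))
  lab <- test_labels(claims, sdates, cfg)
  expect_identical(lab$participant_id, c("A", "B", "C", "D"))
  # NOS code: overall positive, no subtype flag
  expect_identical(unlist(lab[1, c("overall", "SE", "OE", "DE", "nos")]),
                   c(overall = TRUE, SE = FALSE, OE = FALSE, DE = FALSE, nos = TRUE))
  # two subtype codes combine
  expect_identical(unlist(lab[2, c("overall", "OE", "DE")]),
                   c(overall = TRUE, OE = TRUE, DE = TRUE))
  # only code out of window -> all false
  expect_false(any(unlist(lab[3, -1])))
  # no claims at all -> all false
  expect_false(any(unlist(lab[4, -1])))
})

test_that("labels are invariant to claim order/duplication; subtype implies overall", {
  fx <- generate_fixture_small()
  base <- test_labels(fx$claims, fx$surgical, fx$config)
  set.seed(7)
  shuffled <- fx$claims[sample(nrow(fx$claims)), ]
  doubled <- rbind(as.data.frame(fx$claims), as.data.frame(fx$claims))
  expect_equal(test_labels(shuffled, fx$surgical, fx$config), base)
  expect_equal(test_labels(doubled, fx$surgical, fx$config), base)
  expect_true(all(!(base$SE | base$OE | base$DE | base$nos) | base$overall))
  expect_equal(base, fx$expected$test_labels)
})
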