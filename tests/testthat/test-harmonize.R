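test_that("conditional questions merge into their parent with gate semantics", {
  fx <- smoking_fixture()
  hv <- merge_conditional(fx$parent, fx$child, fx$parent_values, fx$child_values)
  # No -> never smoked; Yes+Still -> current; Yes+Quit -> past;
  # missing parent or gated-but-unanswered child -> missing
  expect_equal(hv$values, c("No", "Still", "Quit", NA, NA, "No"))
  expect_setequal(hv$category_order, c("No", "Still", "Quit"))
  # cross-tabulation: no merged value contradicts the parent answer
  tab <- table(parent = fx$parent_values, merged = hv$values, useNA = "no")
  expect_equal(unname(tab["No", c("Still", "Quit")]), c(0L, 0L))
  expect_equal(unname(tab["Yes", "No"]), 0L)
})

test_that("colliding child labels are renamed with the gate prefix", {
  parent <- variable_record("p", "d", "unordered_categorical",
                            levels = c("No", "Yes"))
  child <- variable_record("c", "d", "unordered_categorical",
                           levels = c("No", "Yes"),
                           parent = "p", parent_gate = "Yes")
  hv <- merge_conditional(parent, child, c("No", "Yes", "Yes"),
                          c(NA, "No", "Yes"))
  expect_equal(hv$values, c("No", "Yes:No", "Yes:Yes"))
})

test_that("dictionary errors: bad gate, unknown parent, cycles", {
  parent <- variable_record("p", "d", "unordered_categorical",
                            levels = c("No", "Yes"))
  child <- variable_record("c", "d", "unordered_categorical",
                           levels = c("A", "B"),
                           parent = "p", parent_gate = "Maybe")
  expect_error(merge_conditional(parent, child, "No", "A"),
               class = "enwas_dictionary_error")
  expect_error(enwas_dictionary(list(
    variable_record("a", "d", "continuous", parent = "ghost",
                    parent_gate = "x"))),
    class = "enwas_dictionary_error")
  expect_error(enwas_dictionary(list(
    variable_record("a", "d", "unordered_categorical", levels = c("x", "y"),
                    parent = "b", parent_gate = "x"),
    variable_record("b", "d", "unordered_categorical", levels = c("x", "y"),
                    parent = "a", parent_gate = "x"))),
    class = "enwas_dictionary_error")
})

test_that("'do not know' answers become missing and leave the label set", {
  rec <- variable_record("bw_recall", "perinatal_obstetric",
                         "unordered_categorical",
                         levels = c("Yes", "No", "Do not know"),
                         dont_know_labels = "Do not know")
  hv <- recode_dont_know(rec, c("Yes", "No", "Do not know"))
  expect_equal(hv$values, c("Yes", "No", NA))
  expect_false("Do not know" %in% hv$category_order)
  # no dk labels declared: identity
  rec2 <- variable_record("v", "d", "unordered_categorical",
                          levels = c("Yes", "No"))
  hv2 <- recode_dont_know(rec2, c("Yes", "No"))
  expect_equal(hv2$values, c("Yes", "No"))
  expect_length(hv2$audit, 0L)
  # everything dk: all missing (left for the 50% filter downstream)
  rec3 <- variable_record("v", "d", "unordered_categorical",
                          levels = c("Yes", "Do not know"),
                          dont_know_labels = "Do not know")
  hv3 <- recode_dont_know(rec3, rep("Do not know", 4))
  expect_true(all(is.na(hv3$values)))
})

test_that("category collapsing follows the lopsided / centered / sparse rules", {
  # (a) lopsided ordered 4+ levels
  v <- recode_dont_know(
    variable_record("freq", "d", "ordered_categorical",
                    levels = c("Never", "Rarely", "Sometimes", "Often")),
    values_from_counts(c(Never = 70, Rarely = 15, Sometimes = 10, Often = 5)))
  out <- collapse_categories(v, lopsided_threshold = 0.5)
  expect_equal(out$category_order, c("Never", "Rarely", "Sometimes+Often"))
  expect_equal(sort(unique(out$values)),
               sort(c("Never", "Rarely", "Sometimes+Often")))
  # (b) centered ordered 5+ levels
  v <- recode_dont_know(
    variable_record("agree", "d", "ordered_categorical",
                    levels = c("SD", "D", "N", "A", "SA")),
    values_from_counts(c(SD = 5, D = 15, N = 60, A = 15, SA = 5)))
  out <- collapse_categories(v, centered_threshold = 0.4)
  expect_equal(out$category_order, c("SD+D", "N", "A+SA"))
  # (c) sparse unordered pooled into "other"
  v <- recode_dont_know(
    variable_record("cat", "d", "unordered_categorical",
                    levels = c("A", "B", "C")),
    values_from_counts(c(A = 96, B = 2, C = 2)))
  out <- collapse_categories(v, sparse_threshold = 0.05)
  expect_setequal(out$category_order, c("A", "other"))
  expect_equal(sum(out$values == "other"), 4L)
  # single observed level passes through untouched
  v <- recode_dont_know(
    variable_record("const", "d", "unordered_categorical",
                    levels = c("A", "B")),
    rep("A", 10))
  expect_equal(collapse_categories(v)$values, rep("A", 10))
})

test_that("collapsing never increases levels and maps equal raw values equally", {
  set.seed(31)
  for (i in 1:20) {
    k <- sample(3:7, 1)
    lev <- paste0("L", seq_len(k))
    vals <- sample(lev, 300, TRUE, prob = stats::rgamma(k, 0.6) + 0.05)
    v <- recode_dont_know(
      variable_record("v", "d", "ordered_categorical", levels = lev), vals)
    out <- collapse_categories(v)
    expect_lte(length(out$category_order), k)
    expect_gte(length(out$category_order), 2L)
    # equal raw values -> equal harmonized values
    expect_true(all(tapply(out$values, vals, function(g)
      length(unique(g)) == 1L)))
  }
})

test_that("type classification honors declarations and infers when absent", {
  eth <- variable_record("ethnicity", "sociodemographic", "unordered_categorical",
                         levels = c("Dutch", "Other"))
  expect_equal(classify_variable(eth, c("Dutch", "Other"))$var_type,
               "unordered_categorical")
  edu <- variable_record("education", "sociodemographic", "ordered_categorical",
                         levels = c("low", "mid", "high"))
  expect_equal(classify_variable(edu, c("low", "high"))$var_type,
               "ordered_categorical")
  bw <- variable_record("birth_weight", "perinatal_obstetric", "continuous")
  expect_equal(classify_variable(bw, rnorm(5))$var_type, "continuous")
  # inference: numeric, many distinct values -> continuous, flagged
  undeclared <- variable_record("v", "d", NA_character_)
  cls <- classify_variable(undeclared, as.character(seq(0.1, 9.9, by = 0.7)))
  expect_equal(cls$var_type, "continuous")
  expect_true(cls$inferred)
  # mixed numeric/text without declaration errors
  expect_error(classify_variable(undeclared, c("1.5", "tall", "2")),
               class = "enwas_classification_error")
})

test_that("full-cohort harmonization is replayable and idempotent", {
  coh <- generate_cohort(small_spec(n = 400, seed = 5))
  h <- harmonize_cohort(coh$data, coh$dictionary)
  # round-trip: the audit reconstructs every harmonized column exactly
  for (nm in names(h$dictionary)) {
    expect_equal(audit_replay(h$audit[[nm]], coh$data, nm), h$data[[nm]],
                 info = nm)
  }
  # idempotence: harmonizing the harmonized output changes nothing
  h2 <- harmonize_cohort(h$data, h$dictionary)
  for (nm in names(h$dictionary)) {
    expect_identical(h2$data[[nm]], h$data[[nm]], info = nm)
  }
  # children were merged away, dk labels gone from every level set
  expect_lt(length(h$dictionary), length(coh$dictionary))
  for (r in h$dictionary) {
    expect_false("Do not know" %in% r$levels)
  }
})

test_that("audit log serializes as JSON lines", {
  coh <- generate_cohort(small_spec(n = 150, seed = 6))
  h <- harmonize_cohort(coh$data, coh$dictionary)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_audit(h$audit, path)
  lines <- readLines(path)
  expect_gt(length(lines), 0L)
  rec <- jsonlite::fromJSON(lines[1])
  expect_true(all(c("variable", "step") %in% names(rec)))
})
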