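# Raw table fixture covering the CKD encodings and missing values.
make_raw <- function() {
  data.frame(
    age = c(48, 53, NA, 61),
    bp = c(80, 70, 90, NA),
    sg = c(1.020, 1.010, NA, 1.015),
    al = c(1, 3, 0, NA),
    su = c(0, 0, 1, 0),
    rbc = c("normal", "abnormal", NA, "normal"),
    pc = c("normal", "Abnormal", "normal", "normal"),
    pcc = c("present", "notpresent", "notpresent", NA),
    ba = c("notpresent", "notpresent", "present", "notpresent"),
    bgr = c(121, 140, NA, 131),
    bu = c(36, 70, 50, 45),
    sc = c(1.2, 3.1, 1.8, 2.0),
    sod = c(137, 135, 140, 138),
    pot = c(4.4, 4.9, 4.1, 4.6),
    hemo = c(15.4, 9.6, 11.1, 12.3),
    pcv = c(44, 31, 35, 38),
    wc = c(7800, 6000, 9200, 8400),
    rc = c(5.2, 4.0, 4.4, 4.7),
    htn = c("yes", "no", "yes", "no"),
    dm = c("yes", "no ", "no", "no"),
    cad = c("no", "no", "no", "yes"),
    appet = c("good", "poor", "good", "good"),
    pe = c("no", "yes", "no", "no"),
    ane = c("no", "yes", "no", "no"),
    class = c("ckd", "ckd\t", "notckd", "NOTCKD"),
    stringsAsFactors = FALSE
  )
}

test_that("nominal encoding maps the clinical category scales to codes", {
  enc <- encode_nominal(make_raw(), ckd_schema())
  expect_equal(enc$rbc, c(1, 0, NA, 1))       # normal/abnormal -> 1/0
  expect_equal(enc$appet, c(1, 0, 1, 1))      # good/poor -> 1/0
  expect_equal(enc$pcc[1:3], c(1, 0, 0))      # present/notpresent -> 1/0
  expect_equal(enc$htn, c(1, 0, 1, 0))        # yes/no -> 1/0
  expect_equal(enc$bu, c(36, 70, 50, 45))     # numeric column untouched
  expect_equal(enc$sg[c(1, 2, 4)], c(1.020, 1.010, 1.015))
  # labels matched case-insensitively, whitespace stripped
  expect_equal(enc$pc, c(1, 0, 1, 1))
  expect_equal(enc$dm, c(1, 0, 0, 0))
  expect_equal(enc$class, c(1, 1, -1, -1))    # ckd -> +1, notckd -> -1
})

test_that("unknown category labels are rejected with attribute and value", {
  raw <- make_raw()
  raw$rbc[2] <- "weird"
  expect_error(encode_nominal(raw, ckd_schema()), "rbc.*weird")
  raw <- make_raw()
  raw$class[1] <- "maybe"
  expect_error(encode_nominal(raw, ckd_schema()), "maybe")
})

test_that("mean imputation fills missing entries with observed column means", {
  schema <- attribute_schema(list(
    schema_attribute("v", "numeric"),
    schema_attribute("w", "numeric")
  ))
  raw <- data.frame(v = c(1, 2, NA, 3), w = c(5, 6, 7, 8))
  out <- impute_mean(raw, schema)
  expect_equal(out$v, c(1, 2, 2, 3))
  expect_equal(out$w, raw$w)  # complete column unchanged
  expect_error(impute_mean(data.frame(v = c(NA_real_, NA_real_),
                                      w = c(1, 2)), schema),
               "entirely missing")
})

test_that("imputed values equal independent per-column means of observed entries", {
  set.seed(42)
  gen <- generate_table(ckd_like_config(missing_rate = 0, seed = 11))
  enc <- encode_nominal(gen$table, gen$schema)
  # inject 10% missingness on the encoded table, remembering the truth
  n <- nrow(enc); cols <- schema_names(gen$schema)
  full <- enc
  for (nm in cols) {
    hit <- runif(n) < 0.1
    enc[[nm]][hit] <- NA
  }
  imp <- impute_mean(enc, gen$schema, nominal = "mean")
  for (nm in cols) {
    miss <- is.na(enc[[nm]])
    if (!any(miss)) next
    expected <- mean(enc[[nm]][!miss])  # brute-force column mean oracle
    expect_equal(unique(imp[[nm]][miss]), expected, tolerance = 1e-12)
    expect_equal(imp[[nm]][!miss], full[[nm]][!miss])
  }
})

test_that("rounded nominal imputation keeps codes valid, ties to majority", {
  schema <- attribute_schema(list(
    schema_attribute("b", "binary-nominal", encoding = c(yes = 1, no = 0),
                     scaled = FALSE),
    schema_attribute("m", "multilevel-nominal", levels = 0:5)
  ))
  raw <- data.frame(b = c(1, 1, 0, NA), m = c(0, 1, 5, NA))
  out <- impute_mean(raw, schema)
  expect_equal(out$b[4], 1)            # mean 2/3 rounds to 1
  expect_equal(out$m[4], 2)            # mean 2 is a valid code
  # exact tie between codes 0 and 1: majority of observed entries wins
  raw2 <- data.frame(b = c(1, 0, 0, NA), m = c(0, 0, 1, NA))
  out2 <- impute_mean(raw2, schema)
  expect_equal(out2$b[4], 0)           # mean 1/3 -> nearest code 0
  expect_equal(out2$m[4], 0)           # mean 1/3 -> 0
  raw3 <- data.frame(b = c(1, 1, 0, 0, NA), m = c(1, 1, 2, 2, NA))
  out3 <- impute_mean(raw3, schema)
  expect_true(out3$b[5] %in% c(0, 1))  # tie at 0.5; both codes equally frequent
  expect_equal(out3$m[5], 1)           # tie at 1.5; equal counts -> smaller code
})

test_that("imputation preserves the column mean (plain-mean mode)", {
  schema <- attribute_schema(list(schema_attribute("v", "numeric")))
  set.seed(3)
  v <- rnorm(50); v[sample(50, 10)] <- NA
  out <- impute_mean(data.frame(v = v), schema, nominal = "mean")
  expect_equal(mean(out$v), mean(v, na.rm = TRUE), tolerance = 1e-12)
})

test_that("min-max scaling maps flagged columns onto [0,1], passes others through", {
  schema <- attribute_schema(list(
    schema_attribute("a", "numeric"),
    schema_attribute("b", "binary-nominal", encoding = c(yes = 1, no = 0),
                     scaled = FALSE),
    schema_attribute("age", "numeric", scaled = FALSE)
  ))
  raw <- data.frame(a = c(2, 4, 6), b = c(0, 1, 1), age = c(40, 55, 70),
                    class = c("ckd", "ckd", "notckd"))
  raw <- encode_nominal(raw, schema)
  dm <- scale_minmax(raw, schema)
  expect_equal(unname(dm$X[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(dm$X[, "b"]), c(0, 1, 1))      # binary untouched
  expect_equal(unname(dm$X[, "age"]), c(40, 55, 70)) # age untouched
  expect_equal(dm$y, c(1, 1, -1))
})

test_that("constant scaled column maps to zero with a warning", {
  schema <- attribute_schema(list(schema_attribute("a", "numeric")))
  raw <- data.frame(a = c(5, 5, 5), class = c("ckd", "notckd", "ckd"))
  raw <- encode_nominal(raw, schema)
  expect_warning(dm <- scale_minmax(raw, schema), "constant")
  expect_equal(unname(dm$X[, 1]), c(0, 0, 0))
})

test_that("full pipeline output satisfies the design-matrix contract", {
  gen <- generate_table(ckd_like_config(missing_rate = 0.08, seed = 5))
  dm <- preprocess(gen$table, gen$schema)
  expect_false(anyNA(dm$X))
  expect_true(all(dm$y %in% c(-1, 1)))
  scaled <- schema_scaled(gen$schema)
  for (j in which(scaled)) {
    expect_gte(min(dm$X[, j]), 0)
    expect_lte(max(dm$X[, j]), 1)
    # non-degenerate scaled columns attain both endpoints
    expect_equal(range(dm$X[, j]), c(0, 1))
  }
})

test_that("ARFF and CSV round-trip through the reader, '?' marking missing", {
  gen <- generate_table(ckd_like_config(n_pos = 30, n_neg = 20,
                                        missing_rate = 0.1, seed = 9))
  for (ext in c("arff", "csv")) {
    path <- file.path(tempdir(), paste0("synth.", ext))
    write_clinical_table(gen$table, path)
    back <- read_clinical_table(path, gen$schema)
    expect_equal(names(back), names(gen$table))
    expect_equal(which(is.na(back)), which(is.na(gen$table)))
    dm1 <- preprocess(gen$table, gen$schema)
    dm2 <- preprocess(back, gen$schema)
    expect_equal(dm2$X, dm1$X, tolerance = 1e-9)
    expect_equal(dm2$y, dm1$y)
    unlink(path)
  }
})

test_that("CSV with shuffled header is realigned to the schema", {
  gen <- generate_table(ckd_like_config(n_pos = 10, n_neg = 10,
                                        missing_rate = 0, seed = 2))
  path <- tempfile(fileext = ".csv")
  set.seed(31)
  shuffled <- gen$table[, sample(ncol(gen$table))]
  write_clinical_table(shuffled, path)
  back <- read_clinical_table(path, gen$schema)
  expect_equal(names(back), c(schema_names(gen$schema), "class"))
  expect_equal(preprocess(back, gen$schema)$X,
               preprocess(gen$table, gen$schema)$X, tolerance = 1e-9)
  unlink(path)
})

test_that("tables that do not match the schema are rejected", {
  gen <- generate_table(ckd_like_config(n_pos = 5, n_neg = 5, seed = 1))
  path <- tempfile(fileext = ".csv")
  tab <- gen$table
  names(tab)[3] <- "mystery"
  write_clinical_table(tab, path)
  expect_error(read_clinical_table(path, gen$schema), "sg")
  expect_error(read_clinical_table("no/such/file.csv", gen$schema),
               "not found")
  unlink(path)
})
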