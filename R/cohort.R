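# Synthetic cohort generation: candidate and donor tables with the schema
# the simulator consumes, drawn from configurable marginal distributions.
# Fields are sampled independently of each other; the generator emulates a
# registry extract, not the registry's joint distribution.

CANDIDATE_COLUMNS <- c(
  "id", "age", "sex", "blood_group", "state", "pra",
  "hla_a", "hla_b", "hla_dr",
  "listing_date", "dialysis_start_date", "prior_kidney_transplant",
  "lung_disease", "smoking", "diabetes", "cardiovascular_disease", "cancer"
)

DONOR_COLUMNS <- c(
  "id", "age", "blood_group", "state", "kdri", "donation_date",
  "hla_a", "hla_b", "hla_dr"
)

COMORBIDITY_COLUMNS <- c("lung_disease", "smoking", "diabetes",
                         "cardiovascular_disease", "cancer")

#' Default cohort marginal distributions
#'
#' Reads the packaged marginals config (YAML) describing per-field target
#' distributions: age bands, blood-group / state frequencies, PRA bands,
#' comorbidity prevalences, dialysis-history parameters, a log-normal KDRI
#' model and per-locus HLA allele pools. These are synthetic stand-ins with
#' realistic orders of magnitude, not registry estimates; every value can
#' be overridden by supplying your own file.
#'
#' @param path optional path to a YAML/JSON marginals file; default uses the
#'   packaged one.
#' @return a validated `kap_marginals` list.
#' @export
cohort_marginals <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_marginals.yaml",
                        package = "kapsim", mustWork = TRUE)
  }
  m <- yaml::read_yaml(path)
  validate_marginals(m)
}

#' @rdname cohort_marginals
#' @param m a marginals list to validate.
#' @export
validate_marginals <- function(m) {
  check_cat <- function(p, field) {
    p <- unlist(p)
    kap_assert(all(p >= 0), "marginals field '%s': negative frequency", field,
               class = "kap_validation_error")
    kap_assert(abs(sum(p) - 1) < 1e-9,
               "marginals field '%s': frequencies sum to %.10f, not 1",
               field, sum(p), class = "kap_validation_error")
  }
  check_bands <- function(bands, field) {
    p <- vapply(bands, function(b) as.numeric(b$p), numeric(1))
    check_cat(p, field)
    for (b in bands) {
      kap_assert(b$min <= b$max, "marginals field '%s': band min > max",
                 field, class = "kap_validation_error")
    }
  }
  for (f in c("age", "donor_age", "pra")) check_bands(m[[f]]$bands, f)
  for (f in c("sex", "blood_group", "state")) check_cat(m[[f]], f)
  kap_assert(setequal(names(m$blood_group), BLOOD_GROUPS),
             "marginals field 'blood_group': levels must be O, A, B, AB",
             class = "kap_validation_error")
  kap_assert(all(names(m$state) %in% STATES),
             "marginals field 'state': unknown state code",
             class = "kap_validation_error")
  for (loc in c("A", "B", "DR")) check_cat(m$hla[[loc]], paste0("hla$", loc))
  p <- unlist(m$comorbidity)
  kap_assert(all(p >= 0 & p <= 1),
             "marginals field 'comorbidity': prevalences must lie in [0,1]",
             class = "kap_validation_error")
  kap_assert(m$kdri$sdlog >= 0, "marginals field 'kdri': sdlog must be >= 0",
             class = "kap_validation_error")
  structure(m, class = "kap_marginals")
}

sample_categorical <- function(n, probs) {
  p <- unlist(probs)
  sample(names(p), n, replace = TRUE, prob = p)
}

# Draw uniformly within a band chosen by its probability mass.
sample_banded <- function(n, bands) {
  p <- vapply(bands, function(b) as.numeric(b$p), numeric(1))
  idx <- sample.int(length(bands), n, replace = TRUE, prob = p)
  lo <- vapply(bands, function(b) as.numeric(b$min), numeric(1))[idx]
  hi <- vapply(bands, function(b) as.numeric(b$max), numeric(1))[idx]
  stats::runif(n, lo, hi)
}

sample_hla_locus <- function(n, pool) {
  a1 <- sample_categorical(n, pool)
  a2 <- sample_categorical(n, pool)
  paste(a1, a2, sep = ";")
}

#' Generate a synthetic candidate table
#'
#' Draws `n` waitlist candidates with every field sampled independently
#' from its marginal distribution: banded age and PRA, categorical sex /
#' blood group / state, Bernoulli comorbidity flags, two HLA alleles per
#' locus from the configured pools, listing dates uniform over the
#' configured calendar window, and dialysis start dates placed an
#' exponential number of years before listing for the on-dialysis fraction.
#'
#' @param n number of candidates (>= 0).
#' @param marginals a `kap_marginals` object (default packaged one).
#' @param seed integer seed; identical `(n, marginals, seed)` give
#'   bit-identical tables.
#' @return a data.frame with the candidate schema (see
#'   [read_cohort()] for column meanings).
#' @export
generate_candidates <- function(n, marginals = cohort_marginals(), seed = 1L) {
  marginals <- validate_marginals(marginals)
  kap_assert(n >= 0, "n must be >= 0", class = "kap_validation_error")
  n <- as.integer(n)
  win <- as.Date(c(marginals$dates$start, marginals$dates$end))
  with_local_seed(derive_seed(seed, "candidates"), {
    age <- round(sample_banded(n, marginals$age$bands), 1)
    pra <- round(pmin(100, pmax(0, sample_banded(n, marginals$pra$bands))), 0)
    listing <- win[1] + floor(stats::runif(n, 0, as.numeric(win[2] - win[1]) + 1))
    on_dial <- stats::runif(n) < marginals$dialysis$p_on_dialysis
    years_prior <- stats::rexp(n, rate = 1 / marginals$dialysis$mean_years)
    dial <- listing - round(years_prior * 365.25)
    dial[!on_dial] <- NA
    out <- data.frame(
      id = sprintf("C%06d", seq_len(n)),
      age = age,
      sex = sample_categorical(n, marginals$sex),
      blood_group = sample_categorical(n, marginals$blood_group),
      state = sample_categorical(n, marginals$state),
      pra = pra,
      hla_a = sample_hla_locus(n, marginals$hla$A),
      hla_b = sample_hla_locus(n, marginals$hla$B),
      hla_dr = sample_hla_locus(n, marginals$hla$DR),
      listing_date = listing,
      dialysis_start_date = dial,
      prior_kidney_transplant = stats::runif(n) < marginals$prior_kidney_transplant,
      stringsAsFactors = FALSE
    )
    for (cm in COMORBIDITY_COLUMNS) {
      out[[cm]] <- stats::runif(n) < marginals$comorbidity[[cm]]
    }
    if (n == 0) {
      # preserve full schema and column types on the empty table
      out <- empty_table(CANDIDATE_COLUMNS, candidate_column_types())
    }
    validate_cohort(out, "candidate")
  })
}

#' Generate a synthetic donor table
#'
#' Draws `n` deceased donors with banded age, categorical blood group and
#' state, a log-normal Kidney Donor Risk Index (KDRI; 1.0 = reference
#' donor), two HLA alleles per locus (needed to compute donor-to-recipient
#' mismatch counts) and donation dates uniform over
#' `[start_date, end_date]`.
#'
#' @inheritParams generate_candidates
#' @param start_date,end_date calendar window for donation dates
#'   (default: the marginals' configured window).
#' @return a data.frame with the donor schema.
#' @export
generate_donors <- function(n, marginals = cohort_marginals(), seed = 1L,
                            start_date = NULL, end_date = NULL) {
  marginals <- validate_marginals(marginals)
  kap_assert(n >= 0, "n must be >= 0", class = "kap_validation_error")
  n <- as.integer(n)
  start_date <- as.Date(start_date %||% marginals$dates$start)
  end_date <- as.Date(end_date %||% marginals$dates$end)
  kap_assert(start_date <= end_date, "start_date (%s) is after end_date (%s)",
             start_date, end_date, class = "kap_validation_error")
  with_local_seed(derive_seed(seed, "donors"), {
    out <- data.frame(
      id = sprintf("D%06d", seq_len(n)),
      age = round(sample_banded(n, marginals$donor_age$bands), 1),
      blood_group = sample_categorical(n, marginals$blood_group),
      state = sample_categorical(n, marginals$state),
      kdri = stats::rlnorm(n, meanlog = marginals$kdri$meanlog,
                           sdlog = marginals$kdri$sdlog),
      donation_date = start_date +
        floor(stats::runif(n, 0, as.numeric(end_date - start_date) + 1)),
      hla_a = sample_hla_locus(n, marginals$hla$A),
      hla_b = sample_hla_locus(n, marginals$hla$B),
      hla_dr = sample_hla_locus(n, marginals$hla$DR),
      stringsAsFactors = FALSE
    )
    if (n == 0) out <- empty_table(DONOR_COLUMNS, donor_column_types())
    validate_cohort(out, "donor")
  })
}

candidate_column_types <- function() {
  c(id = "character", age = "numeric", sex = "character",
    blood_group = "character", state = "character", pra = "numeric",
    hla_a = "character", hla_b = "character", hla_dr = "character",
    listing_date = "Date", dialysis_start_date = "Date",
    prior_kidney_transplant = "logical",
    stats::setNames(rep("logical", length(COMORBIDITY_COLUMNS)),
                    COMORBIDITY_COLUMNS))
}

donor_column_types <- function() {
  c(id = "character", age = "numeric", blood_group = "character",
    state = "character", kdri = "numeric", donation_date = "Date",
    hla_a = "character", hla_b = "character", hla_dr = "character")
}

empty_table <- function(cols, types) {
  out <- lapply(cols, function(cl) {
    switch(types[[cl]],
           character = character(0),
           numeric = numeric(0),
           logical = logical(0),
           Date = as.Date(character(0)))
  })
  names(out) <- cols
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Validate a cohort table against its schema
#'
#' Checks column presence, enumerated levels (blood group, state, sex),
#' numeric domains (PRA in `[0, 100]`, KDRI > 0, age in `[0, 130]`) and
#' temporal consistency (dialysis start on or before listing). Pediatric
#' status is derived as `age < 18` and never stored.
#'
#' @param x a data.frame.
#' @param type `"candidate"` or `"donor"`.
#' @return `x` invisibly usable (returned) on success; error otherwise.
#' @export
validate_cohort <- function(x, type = c("candidate", "donor")) {
  type <- match.arg(type)
  cols <- if (type == "candidate") CANDIDATE_COLUMNS else DONOR_COLUMNS
  missing <- setdiff(cols, names(x))
  kap_assert(length(missing) == 0, "missing required column(s): %s",
             paste(missing, collapse = ", "), class = "kap_schema_error")
  kap_assert(!anyDuplicated(x$id), "duplicate ids in %s table", type,
             class = "kap_validation_error")
  kap_assert(all(x$blood_group %in% BLOOD_GROUPS),
             "blood_group outside {O, A, B, AB}",
             class = "kap_validation_error")
  kap_assert(all(x$state %in% STATES), "unknown state code",
             class = "kap_validation_error")
  kap_assert(all(x$age >= 0 & x$age <= 130), "age out of range",
             class = "kap_validation_error")
  if (type == "candidate") {
    kap_assert(all(x$pra >= 0 & x$pra <= 100), "pra outside [0, 100]",
               class = "kap_validation_error")
    kap_assert(all(x$sex %in% c("F", "M")), "sex outside {F, M}",
               class = "kap_validation_error")
    ok <- is.na(x$dialysis_start_date) | x$dialysis_start_date <= x$listing_date
    kap_assert(all(ok), "dialysis_start_date after listing_date",
               class = "kap_validation_error")
  } else {
    kap_assert(all(x$kdri > 0), "kdri must be > 0",
               class = "kap_validation_error")
    kap_assert(!anyNA(x$donation_date), "donation_date missing",
               class = "kap_validation_error")
  }
  x
}

#' Read / write cohort tables as CSV
#'
#' Cohort files are UTF-8 CSV with a header row, ISO-8601 dates, and two
#' semicolon-joined antigen labels per HLA locus (e.g. `"A2;A24"`).
#' A write-then-read round trip reproduces every field exactly. Reading
#' validates the schema: a missing required column raises a schema error
#' naming it, and an unparseable date raises a row-level error with the
#' row index.
#'
#' @param path file path.
#' @param type `"auto"` (detected from the columns), `"candidate"` or
#'   `"donor"`.
#' @return `read_cohort`: a validated data.frame; `write_cohort`: the path,
#'   invisibly.
#' @export
read_cohort <- function(path, type = c("auto", "candidate", "donor")) {
  type <- match.arg(type)
  kap_assert(file.exists(path), "cohort file not found: %s", path,
             class = "kap_io_error")
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (type == "auto") {
    type <- if ("donation_date" %in% names(raw)) "donor" else "candidate"
  }
  types <- if (type == "candidate") candidate_column_types()
           else donor_column_types()
  missing <- setdiff(names(types), names(raw))
  kap_assert(length(missing) == 0, "missing required column(s): %s",
             paste(missing, collapse = ", "), class = "kap_schema_error")
  out <- raw[names(types)]
  for (cl in names(types)) {
    v <- out[[cl]]
    v[v == ""] <- NA
    out[[cl]] <- switch(
      types[[cl]],
      character = v,
      numeric = as.numeric(v),
      logical = as.logical(toupper(v)),
      Date = parse_iso_dates(v, cl)
    )
  }
  validate_cohort(out, type)
}

parse_iso_dates <- function(v, column) {
  d <- as.Date(v, format = "%Y-%m-%d")
  bad <- which(!is.na(v) & is.na(d))
  kap_assert(length(bad) == 0,
             "column '%s': unparseable date at row(s) %s", column,
             paste(utils::head(bad, 5), collapse = ", "),
             class = "kap_validation_error")
  d
}

#' @rdname read_cohort
#' @param x a schema-valid cohort table.
#' @export
write_cohort <- function(x, path) {
  type <- if ("donation_date" %in% names(x)) "donor" else "candidate"
  validate_cohort(x, type)
  out <- x
  for (cl in names(out)) {
    if (inherits(out[[cl]], "Date")) out[[cl]] <- format(out[[cl]], "%Y-%m-%d")
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
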