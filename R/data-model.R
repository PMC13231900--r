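# Longitudinal PK data model: covariates, dosing events, observations,
# subject records, and datasets, plus the NONMEM-style CSV dialect.

#' Baseline covariates for one neonate
#'
#' @param wt body weight (kg), > 0.
#' @param pma postmenstrual age (weeks), > 0 and >= `ga`.
#' @param ga gestational age (weeks).
#' @param pna postnatal age (days), >= 0.
#' @param scr serum creatinine (umol/L), > 0; `NA` when not measured.
#' @param sex `"male"` or `"female"`.
#' @return A list of class `pk_covariates`.
#' @export
pk_covariates <- function(wt, pma, ga, pna, scr = NA_real_, sex = "male") {
  sex <- match.arg(sex, c("male", "female"))
  x <- structure(list(wt = as.numeric(wt), pma = as.numeric(pma),
                      ga = as.numeric(ga), pna = as.numeric(pna),
                      scr = as.numeric(scr), sex = sex),
                 class = "pk_covariates")
  validate_covariates(x)
  x
}

validate_covariates <- function(x, who = "covariates") {
  if (!is.finite(x$wt) || x$wt <= 0)
    stop(who, ": body weight must be positive", call. = FALSE)
  if (!is.finite(x$pma) || x$pma <= 0)
    stop(who, ": PMA must be positive", call. = FALSE)
  if (is.finite(x$ga) && x$pma < x$ga)
    stop(who, ": PMA must be >= GA", call. = FALSE)
  if (!is.finite(x$pna) || x$pna < 0)
    stop(who, ": PNA must be >= 0", call. = FALSE)
  if (!is.na(x$scr) && x$scr <= 0)
    stop(who, ": SCR must be positive when present", call. = FALSE)
  invisible(x)
}

#' Subject record: covariates, dosing history, and observations
#'
#' @param subject_id character or numeric identifier, unique in a dataset.
#' @param covariates a [pk_covariates()] object.
#' @param doses data frame with columns `time` (h since first dose),
#'   `amount` (mg) and `infusion_duration` (h); at least one row.
#' @param observations data frame with columns `time` (h), `conc`
#'   (mg/L whole blood) and logical `blq`; may have zero rows.
#' @return A list of class `pk_subject`.
#' @export
pk_subject <- function(subject_id, covariates, doses, observations) {
  doses <- as.data.frame(doses)
  observations <- as.data.frame(observations)
  if (nrow(observations) && !"blq" %in% names(observations))
    observations$blq <- FALSE
  if (!nrow(observations))
    observations <- data.frame(time = numeric(), conc = numeric(),
                               blq = logical())
  x <- structure(list(subject_id = as.character(subject_id),
                      covariates = covariates,
                      doses = doses[c("time", "amount", "infusion_duration")],
                      observations = observations[c("time", "conc", "blq")]),
                 class = "pk_subject")
  validate_subject(x)
  x
}

validate_subject <- function(s) {
  id <- s$subject_id
  validate_covariates(s$covariates, paste0("subject ", id))
  d <- s$doses
  if (nrow(d) == 0L)
    stop("subject ", id, ": at least one dose event is required",
         call. = FALSE)
  if (any(d$time < 0) || any(d$amount <= 0) || any(d$infusion_duration <= 0))
    stop("subject ", id, ": dose events need time >= 0, amount > 0, ",
         "infusion_duration > 0", call. = FALSE)
  if (is.unsorted(d$time))
    stop("subject ", id, ": dose times must be non-decreasing",
         call. = FALSE)
  o <- s$observations
  if (nrow(o)) {
    if (any(o$time < 0))
      stop("subject ", id, ": observation times must be >= 0",
           call. = FALSE)
    if (is.unsorted(o$time))
      stop("subject ", id, ": observation times must be non-decreasing",
           call. = FALSE)
    if (any(!o$blq & !(is.finite(o$conc) & o$conc > 0)))
      stop("subject ", id, ": non-BLQ concentrations must be positive",
           call. = FALSE)
  }
  invisible(s)
}

#' Assemble a PK dataset from subject records
#'
#' @param subjects list of [pk_subject()] records with unique ids.
#' @param source provenance tag (e.g. a file path or `"synthetic"`).
#' @param seed integer seed when the dataset is synthetic, else `NULL`.
#' @return A list of class `pk_dataset` with elements `subjects`,
#'   `source`, `seed`.
#' @export
pk_dataset <- function(subjects, source = "unspecified", seed = NULL) {
  x <- structure(list(subjects = subjects, source = source, seed = seed),
                 class = "pk_dataset")
  validate_pk_dataset(x)
  x
}

validate_pk_dataset <- function(ds) {
  ids <- vapply(ds$subjects, function(s) s$subject_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate subject ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  lapply(ds$subjects, validate_subject)
  if (sum(vapply(ds$subjects, function(s) nrow(s$observations),
                 integer(1))) == 0L)
    stop("dataset contains no observations", call. = FALSE)
  invisible(ds)
}

#' @export
print.pk_dataset <- function(x, ...) {
  nobs <- sum(vapply(x$subjects, function(s) nrow(s$observations),
                     integer(1)))
  cat("<pk_dataset> ", length(x$subjects), " subjects, ", nobs,
      " observations (source: ", x$source, ")\n", sep = "")
  invisible(x)
}

#' Number of observations in a dataset
#' @param dataset a `pk_dataset`.
#' @return integer count of observation records.
#' @export
n_observations <- function(dataset) {
  sum(vapply(dataset$subjects, function(s) nrow(s$observations),
             integer(1)))
}

# ---- NONMEM-style CSV dialect -------------------------------------------

#' Default column mapping for the NONMEM-style CSV layout
#'
#' Dose rows have `EVID = 1` with `AMT` (mg) and `DUR` (h); observation
#' rows have `EVID = 0`, `MDV = 0` and `DV` (mg/L). `SEX` is coded 1 for
#' male, 0 for female. An optional `BLQ` column carries the
#' below-limit-of-quantification flag; absent that, `DV` below `lloq` is
#' flagged on read.
#'
#' @param ... name overrides, e.g. `dv = "CONC"`.
#' @return named character vector mapping internal fields to CSV headers.
#' @export
nonmem_col_map <- function(...) {
  m <- c(id = "ID", time = "TIME", amt = "AMT", dur = "DUR", dv = "DV",
         evid = "EVID", mdv = "MDV", wt = "WT", pma = "PMA", ga = "GA",
         pna = "PNA", scr = "SCR", sex = "SEX", blq = "BLQ")
  ov <- list(...)
  m[names(ov)] <- unlist(ov)
  m
}

#' Read a PK dataset from a NONMEM-style CSV file
#'
#' @param path CSV file path.
#' @param col_map column mapping, see [nonmem_col_map()].
#' @param lloq lower limit of quantification (mg/L) used to flag BLQ
#'   observations when no explicit flag column is present. Default 0.25.
#' @return a validated [pk_dataset()].
#' @export
read_pk_dataset <- function(path, col_map = nonmem_col_map(), lloq = 0.25) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  mandatory <- c("id", "time", "amt", "dur", "dv", "evid", "mdv",
                 "wt", "pma", "ga", "pna", "scr", "sex")
  for (f in mandatory) {
    if (!col_map[[f]] %in% names(raw))
      stop("missing mandatory column: ", col_map[[f]], call. = FALSE)
  }
  has_blq <- col_map[["blq"]] %in% names(raw)
  g <- function(f) raw[[col_map[[f]]]]
  ids <- as.character(g("id"))
  subjects <- lapply(unique(ids), function(id) {
    rows <- raw[ids == id, , drop = FALSE]
    gi <- function(f) rows[[col_map[[f]]]]
    cov_cols <- c("wt", "pma", "ga", "pna", "scr", "sex")
    for (f in cov_cols) {
      v <- gi(f)
      if (length(unique(v[!is.na(v)])) > 1L)
        stop("subject ", id, ": covariate ", col_map[[f]],
             " varies within subject", call. = FALSE)
    }
    first <- function(f) {
      v <- gi(f)
      v <- v[!is.na(v)]
      if (length(v)) v[1L] else NA_real_
    }
    cov <- pk_covariates(wt = first("wt"), pma = first("pma"),
                         ga = first("ga"), pna = first("pna"),
                         scr = first("scr"),
                         sex = if (first("sex") %in% c(1, "male", "M"))
                           "male" else "female")
    is_dose <- gi("evid") == 1
    is_obs <- gi("evid") == 0 & gi("mdv") == 0
    doses <- data.frame(time = gi("time")[is_dose],
                        amount = gi("amt")[is_dose],
                        infusion_duration = gi("dur")[is_dose])
    dv <- gi("dv")[is_obs]
    blq <- if (has_blq) as.logical(gi("blq")[is_obs]) else dv < lloq
    obs <- data.frame(time = gi("time")[is_obs], conc = dv, blq = blq)
    pk_subject(id, cov, doses, obs)
  })
  pk_dataset(subjects, source = path)
}

#' Convert a PK dataset to the NONMEM-style flat table
#'
#' @param x a `pk_dataset`.
#' @param row.names,optional,... ignored (base generic signature).
#' @return data frame with columns ID, TIME, AMT, DUR, DV, EVID, MDV,
#'   BLQ, WT, PMA, GA, PNA, SCR, SEX.
#' @export
as.data.frame.pk_dataset <- function(x, row.names = NULL,
                                     optional = FALSE, ...) {
  rows <- lapply(x$subjects, function(s) {
    cv <- s$covariates
    mk <- function(time, amt, dur, dv, evid, mdv, blq) {
      data.frame(ID = s$subject_id, TIME = time, AMT = amt, DUR = dur,
                 DV = dv, EVID = evid, MDV = mdv, BLQ = blq,
                 WT = cv$wt, PMA = cv$pma, GA = cv$ga, PNA = cv$pna,
                 SCR = cv$scr, SEX = if (cv$sex == "male") 1L else 0L)
    }
    d <- mk(s$doses$time, s$doses$amount, s$doses$infusion_duration,
            NA_real_, 1L, 1L, FALSE)
    o <- s$observations
    out <- if (nrow(o))
      rbind(d, mk(o$time, NA_real_, NA_real_, o$conc, 0L, 0L, o$blq))
    else d
    out[order(out$TIME, -out$EVID), ]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a PK dataset as NONMEM-style CSV
#'
#' The written file round-trips through [read_pk_dataset()] without loss,
#' including BLQ flags (an explicit `BLQ` column is emitted).
#'
#' @param dataset a `pk_dataset`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_pk_dataset <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# ---- covariate preparation ----------------------------------------------

#' Impute missing serum creatinine with the cohort mean
#'
#' Missing SCR values are replaced by the unweighted arithmetic mean of
#' the observed per-subject SCR values. An imputation report (count and
#' rate) is attached as attribute `"scr_imputation"`. Missing rates above
#' 5% trigger a warning, since mean imputation is only considered safe at
#' low missingness.
#'
#' @param dataset a `pk_dataset` with at least one non-missing SCR.
#' @return the dataset with SCR completed.
#' @export
impute_missing_scr <- function(dataset) {
  scr <- vapply(dataset$subjects, function(s) s$covariates$scr, numeric(1))
  miss <- is.na(scr)
  if (all(miss)) stop("all SCR values are missing", call. = FALSE)
  rate <- 100 * mean(miss)
  if (rate > 5)
    warning(sprintf("SCR missing rate %.1f%% exceeds 5%%; mean imputation may be unreliable",
                    rate), call. = FALSE)
  m <- mean(scr[!miss])
  for (i in which(miss)) dataset$subjects[[i]]$covariates$scr <- m
  attr(dataset, "scr_imputation") <- list(n_missing = sum(miss),
                                          n_subjects = length(scr),
                                          rate_percent = rate,
                                          imputed_value = m)
  dataset
}

#' Handle below-limit-of-quantification observations
#'
#' @param dataset a `pk_dataset`.
#' @param policy `"discard"` drops BLQ observations (M1 method, default);
#'   `"loq/2"` replaces their concentration with `lloq / 2`.
#' @param lloq lower limit of quantification (mg/L).
#' @return the dataset with BLQ records handled; the number of affected
#'   records is attached as attribute `"n_blq"`.
#' @export
handle_blq <- function(dataset, policy = c("discard", "loq/2"),
                       lloq = 0.25) {
  if (!is.character(policy) || !all(policy %in% c("discard", "loq/2")))
    stop("unknown BLQ policy: ", paste(policy, collapse = ", "),
         call. = FALSE)
  policy <- match.arg(policy)
  n_blq <- 0L
  for (i in seq_along(dataset$subjects)) {
    o <- dataset$subjects[[i]]$observations
    hit <- o$blq
    n_blq <- n_blq + sum(hit)
    if (!any(hit)) next
    if (policy == "discard") {
      dataset$subjects[[i]]$observations <- o[!hit, , drop = FALSE]
    } else {
      o$conc[hit] <- lloq / 2
      o$blq[hit] <- FALSE
      dataset$subjects[[i]]$observations <- o
    }
  }
  attr(dataset, "n_blq") <- n_blq
  dataset
}
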