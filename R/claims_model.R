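# Data model for monthly claims lines, patient rosters, codebooks and the
# observation window. Months are the atomic time unit throughout: criteria are
# defined month-wise, so days are never parsed.

CODE_TYPES <- c("DX", "RX", "PR")
MONTH_RE <- "^[0-9]{4}-(0[1-9]|1[0-2])$"

#' Normalize a medical code
#'
#' Uppercases, strips surrounding whitespace and removes dots, so that ICD-10
#' dialect differences ("K50.0" vs "K500", "k50") never affect matching.
#' Idempotent.
#'
#' @param raw Character vector of raw codes.
#' @return Character vector of normalized codes.
#' @examples
#' normalize_code(c("K50.0", " k51 "))
#' @export
normalize_code <- function(raw) {
  if (length(raw) == 0L) return(character())
  x <- gsub(".", "", trimws(toupper(as.character(raw))), fixed = TRUE)
  bad <- is.na(x) | x == ""
  if (any(bad)) {
    stop_format("empty or blank code(s): ",
                paste(utils::head(sprintf("'%s'", raw[bad]), 5L), collapse = ", "))
  }
  x
}

#' Match normalized codes against a set of code prefixes
#'
#' A chapter-level prefix denotes all of its subcodes: `"K50"` matches
#' `"K500"`, `"K501"`, ... but `"K500"` does not match `"K50"`.
#'
#' @param code Character vector of normalized codes.
#' @param prefixes Character vector of normalized prefixes.
#' @return Logical vector, `TRUE` where some prefix is a leading substring.
#' @export
code_matches <- function(code, prefixes) {
  if (length(code) == 0L) return(logical())
  if (length(prefixes) == 0L) return(rep(FALSE, length(code)))
  Reduce(`|`, lapply(prefixes, function(p) startsWith(code, p)))
}

# ---- calendar months ---------------------------------------------------------

# integer month index: year * 12 + (month - 1); label form "YYYY-MM"
month_id <- function(label) {
  label <- as.character(label)
  ok <- grepl(MONTH_RE, label)
  if (any(!ok & !is.na(label))) {
    stop_format("malformed month label(s): ",
                paste(utils::head(unique(label[!ok]), 5L), collapse = ", "),
                " (expected YYYY-MM)")
  }
  y <- as.integer(substr(label, 1L, 4L))
  m <- as.integer(substr(label, 6L, 7L))
  y * 12L + (m - 1L)
}

month_label <- function(id) {
  out <- rep(NA_character_, length(id))
  ok <- !is.na(id)
  out[ok] <- sprintf("%04d-%02d", id[ok] %/% 12L, id[ok] %% 12L + 1L)
  out
}

#' Observation window of calendar months
#'
#' @param start,end Month labels `"YYYY-MM"`, inclusive. `start` may also be a
#'   single string `"YYYY-MM:YYYY-MM"`.
#' @return An `obs_window` object.
#' @examples
#' obs_window("2015-01", "2019-12")
#' obs_window("2015-01:2019-12")
#' @export
obs_window <- function(start, end = NULL) {
  if (is.null(end) && length(start) == 1L && grepl(":", start, fixed = TRUE)) {
    parts <- strsplit(start, ":", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) stop_format("window must be 'YYYY-MM:YYYY-MM'")
    start <- parts[1L]; end <- parts[2L]
  }
  s <- month_id(start); e <- month_id(end)
  if (length(s) != 1L || length(e) != 1L || is.na(s) || is.na(e))
    stop_format("window start and end must each be one month label")
  if (s > e) stop_domain("window start ", month_label(s), " is after end ", month_label(e))
  structure(list(start = s, end = e), class = "obs_window")
}

#' @export
print.obs_window <- function(x, ...) {
  cat("<obs_window> ", month_label(x$start), " .. ", month_label(x$end),
      " (", x$end - x$start + 1L, " months)\n", sep = "")
  invisible(x)
}

window_length <- function(window) window$end - window$start + 1L

# ---- codebook ---------------------------------------------------------------

#' Codebook of diagnosis prefixes and prescription/procedure code sets
#'
#' Defines the case-finding vocabulary: ICD-10 prefixes identifying the target
#' disease (Crohn's disease, `K50`), exclusion prefixes whose confirmed
#' presence in the same month vetoes it (ulcerative colitis `K51`, Behcet's
#' disease `M35`), and the sets of disease-specific prescription and
#' surgical/procedure codes. All codes are normalized on construction.
#'
#' @param cd_dx_prefixes Target diagnosis prefixes (default `"K50"`).
#' @param excl_dx_prefixes Exclusion diagnosis prefixes (default `K51`, `M35`).
#' @param cd_rx_codes Disease-specific prescription codes; must be non-empty.
#' @param cd_pr_codes Disease-specific procedure/surgery codes; may be empty.
#' @return A `codebook` object (list of four character vectors).
#' @seealso [default_codebook()], [read_codebook()]
#' @export
codebook <- function(cd_dx_prefixes = "K50",
                     excl_dx_prefixes = c("K51", "M35"),
                     cd_rx_codes,
                     cd_pr_codes = character()) {
  dx <- unique(normalize_code(cd_dx_prefixes))
  ex <- unique(normalize_code(excl_dx_prefixes))
  rx <- unique(normalize_code(cd_rx_codes))
  pr <- if (length(cd_pr_codes)) unique(normalize_code(cd_pr_codes)) else character()
  if (length(dx) == 0L || length(ex) == 0L || length(rx) == 0L)
    stop_domain("cd_dx_prefixes, excl_dx_prefixes and cd_rx_codes must be non-empty")
  if (length(intersect(dx, ex)))
    stop_domain("target and exclusion prefixes overlap after normalization: ",
                paste(intersect(dx, ex), collapse = ", "))
  structure(list(cd_dx_prefixes = dx, excl_dx_prefixes = ex,
                 cd_rx_codes = rx, cd_pr_codes = pr),
            class = "codebook")
}

#' @export
print.codebook <- function(x, ...) {
  cat("<codebook>\n")
  cat("  target dx prefixes  :", paste(x$cd_dx_prefixes, collapse = ", "), "\n")
  cat("  exclusion prefixes  :", paste(x$excl_dx_prefixes, collapse = ", "), "\n")
  cat("  prescription codes  :", length(x$cd_rx_codes), "\n")
  cat("  procedure codes     :", length(x$cd_pr_codes), "\n")
  invisible(x)
}

#' Default codebook with placeholder drug and surgery codes
#'
#' The prescription list names the drug classes used for Crohn's disease
#' (mesalazine, thiopurine immunomodulators, elemental diet, budesonide,
#' infliximab and its biosimilar, adalimumab, ustekinumab, vedolizumab) as
#' synthetic placeholder codes, not national fee-schedule codes: real analyses
#' must supply their own codebook file.
#'
#' @return A `codebook` object.
#' @export
default_codebook <- function() {
  codebook(
    cd_dx_prefixes = "K50",
    excl_dx_prefixes = c("K51", "M35"),
    cd_rx_codes = c("RX_MESALAZINE", "RX_THIOPURINE", "RX_ELEMENTAL_DIET",
                    "RX_BUDESONIDE", "RX_INFLIXIMAB", "RX_INFLIXIMAB_BS",
                    "RX_ADALIMUMAB", "RX_USTEKINUMAB", "RX_VEDOLIZUMAB"),
    cd_pr_codes = c("PR_CD_INTESTINAL_SURGERY", "PR_CD_ANAL_SURGERY")
  )
}

#' Read / write a codebook YAML file
#'
#' Keys: `cd_dx_prefixes`, `excl_dx_prefixes`, `cd_rx_codes`, `cd_pr_codes`.
#'
#' @param path Path to a YAML file.
#' @return `read_codebook` returns a `codebook`; `write_codebook` returns
#'   `path` invisibly.
#' @export
read_codebook <- function(path) {
  raw <- yaml::read_yaml(path)
  need <- c("cd_dx_prefixes", "excl_dx_prefixes", "cd_rx_codes")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop_format("codebook file lacks key(s): ", paste(miss, collapse = ", "))
  codebook(cd_dx_prefixes = unlist(raw$cd_dx_prefixes),
           excl_dx_prefixes = unlist(raw$excl_dx_prefixes),
           cd_rx_codes = unlist(raw$cd_rx_codes),
           cd_pr_codes = unlist(raw$cd_pr_codes))
}

#' @rdname read_codebook
#' @param cb A `codebook` object.
#' @export
write_codebook <- function(cb, path) {
  stopifnot(inherits(cb, "codebook"))
  yaml::write_yaml(lapply(unclass(cb), as.list), path)
  invisible(path)
}

# ---- claims and roster I/O --------------------------------------------------

validate_claims <- function(dt, file = "<claims>") {
  need <- c("patient_id", "month", "code_type", "code", "suspected")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop_format(file, ": missing column(s): ", paste(miss, collapse = ", "))
  rows <- function(bad) paste(utils::head(which(bad), 5L), collapse = ", ")

  bad <- !grepl(MONTH_RE, dt$month)
  if (any(bad)) stop_format(file, ": malformed month at row(s) ", rows(bad))
  bad <- !(dt$code_type %in% CODE_TYPES)
  if (any(bad)) stop_format(file, ": unknown code_type at row(s) ", rows(bad),
                            " (expected DX, RX or PR)")
  code <- as.character(dt$code)
  bad <- is.na(code) | trimws(code) == ""
  if (any(bad)) stop_format(file, ": empty code at row(s) ", rows(bad))
  susp <- dt$suspected
  if (!is.logical(susp)) {
    bad <- !(as.character(susp) %in% c("0", "1"))
    if (any(bad)) stop_format(file, ": suspected must be 0 or 1 at row(s) ", rows(bad))
    susp <- as.character(susp) == "1"
  }
  bad <- susp & dt$code_type != "DX"
  if (any(bad)) stop_format(file, ": suspected flag set on non-DX line at row(s) ", rows(bad))

  out <- data.table::data.table(
    patient_id = as.character(dt$patient_id),
    month = as.character(dt$month),
    code_type = as.character(dt$code_type),
    code = normalize_code(code),
    suspected = susp
  )
  out[, month_id := month_id(month)]
  out[]
}

#' Read a claims CSV
#'
#' Schema (UTF-8, header): `patient_id,month,code_type,code,suspected` with
#' `month` as `YYYY-MM`, `code_type` one of DX/RX/PR and `suspected` 0/1
#' (meaningful only for DX lines). Codes are normalized on read. Lines outside
#' the observation window are dropped with a message reporting the count.
#'
#' @param path CSV path.
#' @param window Optional [obs_window()]; when given, out-of-window lines are
#'   dropped.
#' @return A `data.table` of claim lines with an integer `month_id` helper
#'   column and attributes `n_dropped` and `window`.
#' @export
read_claims <- function(path, window = NULL) {
  dt <- data.table::fread(path, colClasses = list(character = c("patient_id", "month", "code_type", "code")),
                          showProgress = FALSE)
  dt <- validate_claims(dt, file = path)
  n_dropped <- 0L
  if (!is.null(window)) {
    stopifnot(inherits(window, "obs_window"))
    keep <- dt$month_id >= window$start & dt$month_id <= window$end
    n_dropped <- sum(!keep)
    if (n_dropped > 0L)
      message(n_dropped, " claim line(s) outside ", month_label(window$start),
              "..", month_label(window$end), " dropped")
    dt <- dt[keep]
  }
  data.table::setattr(dt, "n_dropped", n_dropped)
  data.table::setattr(dt, "window", window)
  dt[]
}

#' Write a claims table to CSV
#'
#' Inverse of [read_claims()]: round-trips line-for-line (order-insensitive).
#'
#' @param claims Claims table (`patient_id,month,code_type,code,suspected`).
#' @param path Output CSV path.
#' @export
write_claims <- function(claims, path) {
  out <- data.table::as.data.table(claims)[
    , .(patient_id, month, code_type, code, suspected = as.integer(suspected))]
  data.table::fwrite(out, path)
  invisible(path)
}

#' Read / write a patient roster CSV
#'
#' Schema: `patient_id,birth_year,sex` with sex in M/F/U. Patient ids must be
#' unique.
#'
#' @param path CSV path.
#' @return A `data.table` with columns `patient_id`, `birth_year`, `sex`.
#' @export
read_patients <- function(path) {
  dt <- data.table::fread(path, colClasses = list(character = c("patient_id", "sex")),
                          showProgress = FALSE)
  miss <- setdiff(c("patient_id", "birth_year", "sex"), names(dt))
  if (length(miss)) stop_format(path, ": missing column(s): ", paste(miss, collapse = ", "))
  dt[, patient_id := as.character(patient_id)]
  dt[, birth_year := as.integer(birth_year)]
  if (anyDuplicated(dt$patient_id))
    stop_format(path, ": duplicate patient_id(s): ",
                paste(utils::head(unique(dt$patient_id[duplicated(dt$patient_id)]), 5L), collapse = ", "))
  if (any(!(dt$sex %in% c("M", "F", "U"))))
    stop_format(path, ": sex must be M, F or U")
  dt[]
}

#' @rdname read_patients
#' @param patients Roster table.
#' @export
write_patients <- function(patients, path) {
  data.table::fwrite(data.table::as.data.table(patients)[, .(patient_id, birth_year, sex)], path)
  invisible(path)
}
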