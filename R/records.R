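#' Default acute oral toxicity category bounds
#'
#' The five ordered acute oral toxicity categories are defined by LD50
#' cut values in mg/kg body weight, mirroring the EU CLP acute oral
#' bands with an appended low-concern Category 5 (LD50 >= 2000 mg/kg):
#' Category 1 < 5, Category 2 in \[5, 50), Category 3 in \[50, 300),
#' Category 4 in \[300, 2000), Category 5 >= 2000. The printed integer
#' band ends ("5-49", "50-299", ...) are implemented as half-open
#' intervals so that non-integer LD50 values fall in exactly one band.
#'
#' @param lower_edges Strictly increasing numeric vector of four LD50
#'   cut values (mg/kg) separating the five categories.
#' @return An object of class `category_bounds`.
#' @examples
#' category_bounds()
#' categorize(c(4, 5, 50, 2000), category_bounds())
#' @export
category_bounds <- function(lower_edges = c(5, 50, 300, 2000)) {
  if (length(lower_edges) != 4L || anyNA(lower_edges)) {
    stop("`lower_edges` must be four non-missing LD50 cut values (mg/kg)",
         call. = FALSE)
  }
  if (any(diff(lower_edges) <= 0) || any(lower_edges <= 0)) {
    stop("`lower_edges` must be positive and strictly increasing", call. = FALSE)
  }
  structure(list(lower_edges = as.numeric(lower_edges)),
            class = "category_bounds")
}

#' @export
print.category_bounds <- function(x, ...) {
  e <- x$lower_edges
  cat("Acute oral toxicity category bounds (LD50, mg/kg bw):\n")
  cat(sprintf("  1: < %g\n", e[1]))
  for (k in 2:4) cat(sprintf("  %d: [%g, %g)\n", k, e[k - 1], e[k]))
  cat(sprintf("  5: >= %g\n", e[4]))
  invisible(x)
}

#' Assign acute oral toxicity categories from LD50
#'
#' Maps LD50 values (mg/kg body weight) onto the ordinal categories
#' 1-5, where 1 is most toxic (LD50 < 5 mg/kg) and 5 least
#' (LD50 >= 2000 mg/kg). Intervals are half-open: an LD50 exactly at a
#' cut value belongs to the less toxic band (50 mg/kg is Category 3).
#'
#' @param ld50 Numeric vector of LD50 values in mg/kg; must be positive.
#' @param bounds A [category_bounds()] object.
#' @return Integer vector of categories in 1..5, `NA` propagated.
#' @export
categorize <- function(ld50, bounds = category_bounds()) {
  stopifnot(inherits(bounds, "category_bounds"))
  if (!is.numeric(ld50)) stop("`ld50` must be numeric", call. = FALSE)
  ok <- !is.na(ld50)
  if (any(ld50[ok] <= 0)) {
    stop("LD50 values must be positive (mg/kg)", call. = FALSE)
  }
  # findInterval with left-closed intervals: ld50 in [edge_k, edge_{k+1}) -> k
  out <- rep(NA_integer_, length(ld50))
  out[ok] <- findInterval(ld50[ok], bounds$lower_edges,
                          left.open = FALSE) + 1L
  out
}

#' Convert LD50 from mg/kg to log10 mmol/kg
#'
#' LD50 in mg/kg divided by molecular weight (g/mol) gives mmol/kg;
#' the model scale is its base-10 logarithm.
#'
#' @param ld50_mg_kg Positive LD50 in mg/kg body weight.
#' @param mol_weight Positive molecular weight in g/mol.
#' @return log10(ld50 / mol_weight), `NA` where either input is missing.
#' @export
to_log_mmol_kg <- function(ld50_mg_kg, mol_weight) {
  if (!is.numeric(ld50_mg_kg) || !is.numeric(mol_weight)) {
    stop("inputs must be numeric", call. = FALSE)
  }
  if (any(ld50_mg_kg <= 0, na.rm = TRUE) || any(mol_weight <= 0, na.rm = TRUE)) {
    stop("LD50 and molecular weight must be positive", call. = FALSE)
  }
  log10(ld50_mg_kg / mol_weight)
}

#' Validate SMILES strings through the cheminformatics backend
#'
#' Attempts a batch conversion first (the common all-valid case), and
#' falls back to per-row parsing to pinpoint failures.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Logical vector: `TRUE` where the backend parsed the string.
#' @export
smiles_parseable <- function(smiles) {
  n <- length(smiles)
  if (n == 0L) return(logical(0))
  named <- stats::setNames(as.character(smiles), sprintf("s%06d", seq_len(n)))
  batch <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(named)),
    error = function(e) NULL
  )
  if (!is.null(batch) && length(batch) == n) return(rep(TRUE, n))
  vapply(named, function(s) {
    if (is.na(s) || !nzchar(s)) return(FALSE)
    one <- tryCatch(
      suppressWarnings(ChemmineR::smiles2sdf(c(q000001 = s))),
      error = function(e) NULL
    )
    !is.null(one) && length(one) == 1L && all(ChemmineR::validSDF(one))
  }, logical(1), USE.NAMES = FALSE)
}

default_column_map <- function() {
  c(compound_id = "id", smiles = "smiles", casrn = "casrn",
    mol_weight = "mw", ld50_mg_kg = "ld50_mg_kg",
    cramer_class = "cramer_class", test_pred = "test_pred",
    rf_pred = "rf_pred", ac50_log = "ac50_log",
    ac50_censored = "ac50_censored", alert_names = "alert_names")
}

#' Read a compound table into a record data frame
#'
#' Reads a UTF-8 comma-delimited table with a header row and returns a
#' validated compound record data frame. Rows with unparseable SMILES
#' or duplicated identifiers are excluded, with counts attached (and a
#' message emitted), mirroring the curation step of removing duplicate
#' entries and structures that cannot be defined. Missing molecular
#' weights are filled from the parsed structure when
#' `fill_mol_weight = TRUE`.
#'
#' @param path Path to the delimited file.
#' @param column_map Named character vector mapping record fields to
#'   file column names; see `toxtiers:::default_column_map()`. Only
#'   `compound_id` and `smiles` are mandatory.
#' @param validate_structures Check SMILES through the backend and drop
#'   failures (default `TRUE`).
#' @param fill_mol_weight Compute missing molecular weights from the
#'   parsed structure (default `TRUE`).
#' @return A `compound_records` data frame with columns `compound_id`,
#'   `smiles`, `casrn`, `mol_weight`, `ld50_mg_kg`, `log_ld50_mmol_kg`,
#'   `experimental_category`, `cramer_class`, `test_pred`, `rf_pred`,
#'   `ac50_log`, `ac50_censored`, `alert_names` (list column), and
#'   attributes `n_excluded_duplicate` / `n_excluded_structure`.
#' @export
read_compound_table <- function(path, column_map = default_column_map(),
                                validate_structures = TRUE,
                                fill_mol_weight = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, fileEncoding = "UTF-8")
  map <- default_column_map()
  map[names(column_map)] <- column_map
  for (field in c("compound_id", "smiles")) {
    if (!map[[field]] %in% names(raw)) {
      stop(sprintf("mandatory column '%s' (field %s) absent from %s",
                   map[[field]], field, path), call. = FALSE)
    }
  }
  pick_chr <- function(field) {
    col <- map[[field]]
    if (col %in% names(raw)) as.character(raw[[col]]) else rep(NA_character_, nrow(raw))
  }
  pick_num <- function(field) {
    col <- map[[field]]
    if (!col %in% names(raw)) return(rep(NA_real_, nrow(raw)))
    v <- raw[[col]]
    if (is.numeric(v)) return(as.numeric(v))
    v <- trimws(as.character(v))
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & nzchar(v) & is.na(out))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' in column '%s' (row %d, id %s)",
                   v[bad[1]], col, bad[1],
                   as.character(raw[[map[["compound_id"]]]])[bad[1]]),
           call. = FALSE)
    }
    out
  }

  rec <- data.frame(
    compound_id = pick_chr("compound_id"),
    smiles      = pick_chr("smiles"),
    casrn       = pick_chr("casrn"),
    mol_weight  = pick_num("mol_weight"),
    ld50_mg_kg  = pick_num("ld50_mg_kg"),
    cramer_class = pick_chr("cramer_class"),
    test_pred   = pick_num("test_pred"),
    rf_pred     = pick_num("rf_pred"),
    ac50_log    = pick_num("ac50_log"),
    stringsAsFactors = FALSE
  )
  cens <- map[["ac50_censored"]]
  rec$ac50_censored <- if (cens %in% names(raw)) {
    as.logical(raw[[cens]])
  } else rep(NA, nrow(raw))
  al <- map[["alert_names"]]
  rec$alert_names <- if (al %in% names(raw)) {
    lapply(strsplit(as.character(raw[[al]]), ";", fixed = TRUE),
           function(x) x[nzchar(trimws(x))])
  } else rep(list(character(0)), nrow(raw))

  dup <- duplicated(rec$compound_id)
  n_dup <- sum(dup)
  rec <- rec[!dup, , drop = FALSE]

  n_bad_smiles <- 0L
  if (validate_structures && nrow(rec)) {
    ok <- smiles_parseable(rec$smiles)
    n_bad_smiles <- sum(!ok)
    rec <- rec[ok, , drop = FALSE]
  }
  if (n_dup || n_bad_smiles) {
    message(sprintf("read_compound_table: excluded %d duplicated id(s), %d unparseable structure(s)",
                    n_dup, n_bad_smiles))
  }
  rownames(rec) <- NULL
  as_compound_records(rec, fill_mol_weight = fill_mol_weight,
                      n_excluded_duplicate = n_dup,
                      n_excluded_structure = n_bad_smiles)
}

#' Coerce and validate a compound record data frame
#'
#' Enforces the record invariants: positive LD50 and molecular weight,
#' `log_ld50_mmol_kg` consistent with `ld50_mg_kg / mol_weight`, and an
#' experimental category equal to `categorize(ld50_mg_kg)`. Derived
#' columns are (re)computed rather than trusted.
#'
#' @param df Data frame with at least `compound_id` and `smiles`.
#' @param bounds [category_bounds()] used for the derived category.
#' @param fill_mol_weight Compute missing molecular weights from the
#'   structure backend.
#' @param n_excluded_duplicate,n_excluded_structure Exclusion counts to
#'   record as attributes.
#' @return The validated `compound_records` data frame.
#' @export
as_compound_records <- function(df, bounds = category_bounds(),
                                fill_mol_weight = FALSE,
                                n_excluded_duplicate = 0L,
                                n_excluded_structure = 0L) {
  stopifnot(is.data.frame(df))
  need <- c("compound_id", "smiles")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing record column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  opt_num <- c("mol_weight", "ld50_mg_kg", "test_pred", "rf_pred", "ac50_log")
  for (col in opt_num) {
    if (!col %in% names(df)) df[[col]] <- rep(NA_real_, nrow(df))
  }
  if (!"casrn" %in% names(df)) df$casrn <- rep(NA_character_, nrow(df))
  if (!"cramer_class" %in% names(df)) df$cramer_class <- rep(NA_character_, nrow(df))
  if (!"ac50_censored" %in% names(df)) df$ac50_censored <- rep(NA, nrow(df))
  if (!"alert_names" %in% names(df)) df$alert_names <- rep(list(character(0)), nrow(df))
  if (anyDuplicated(df$compound_id)) {
    stop("duplicated compound_id in record table", call. = FALSE)
  }
  if (any(!is.na(df$ld50_mg_kg) & df$ld50_mg_kg <= 0)) {
    stop("ld50_mg_kg must be positive where present", call. = FALSE)
  }
  if (any(!is.na(df$mol_weight) & df$mol_weight <= 0)) {
    stop("mol_weight must be positive where present", call. = FALSE)
  }
  cls <- toupper(trimws(as.character(df$cramer_class)))
  cls[is.na(cls) | !nzchar(cls)] <- "UNASSIGNED"
  bad_cls <- !cls %in% c("I", "II", "III", "UNASSIGNED")
  if (any(bad_cls)) {
    stop("invalid Cramer class value(s): ",
         paste(unique(cls[bad_cls]), collapse = ", "), call. = FALSE)
  }
  df$cramer_class <- cls
  if (fill_mol_weight) {
    need_mw <- which(is.na(df$mol_weight))
    if (length(need_mw)) {
      df$mol_weight[need_mw] <- backend_mol_weight(df$smiles[need_mw])
    }
  }
  has_both <- !is.na(df$ld50_mg_kg) & !is.na(df$mol_weight)
  df$log_ld50_mmol_kg <- rep(NA_real_, nrow(df))
  df$log_ld50_mmol_kg[has_both] <-
    to_log_mmol_kg(df$ld50_mg_kg[has_both], df$mol_weight[has_both])
  df$experimental_category <- categorize(df$ld50_mg_kg, bounds)
  attr(df, "n_excluded_duplicate") <- as.integer(n_excluded_duplicate)
  attr(df, "n_excluded_structure") <- as.integer(n_excluded_structure)
  class(df) <- unique(c("compound_records", class(df)))
  df
}

#' Molecular weights from SMILES via the structure backend
#'
#' @param smiles Character vector of SMILES.
#' @return Numeric vector of molecular weights (g/mol); `NA` where the
#'   structure fails to parse.
#' @keywords internal
backend_mol_weight <- function(smiles) {
  uniq <- unique(smiles)
  mw <- rep(NA_real_, length(uniq))
  ok <- smiles_parseable(uniq)
  if (any(ok)) {
    sdf <- suppressWarnings(
      ChemmineR::smiles2sdf(stats::setNames(uniq[ok], sprintf("m%06d", which(ok))))
    )
    # propOB accounts for implicit hydrogens (ChemmineR::MW does not)
    mw[ok] <- ChemmineR::propOB(sdf)$MW
  }
  mw[match(smiles, uniq)]
}

#' Write a compound record table to CSV
#'
#' @param records A `compound_records` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_compound_table <- function(records, path) {
  out <- as.data.frame(records)
  out$alert_names <- vapply(out$alert_names, paste, "", collapse = ";")
  names(out)[names(out) == "compound_id"] <- "id"
  names(out)[names(out) == "mol_weight"] <- "mw"
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
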