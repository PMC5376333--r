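# Specimen-table ingestion, vaginal-fold cleaning rules, species means,
# log10 transformation, and the non-phylogenetic residual regression.

# Canonical column names and their accepted aliases (matched case-insensitively
# after trimming).  body lengths and vaginal lengths are centimetres, fold
# measurements millimetres.
.specimen_aliases <- list(
  specimen_id               = c("specimen_id", "id", "specimen"),
  species                   = c("species", "binomial", "taxon"),
  body_length_cm            = c("body_length_cm", "body_length", "bl_cm", "bl"),
  vaginal_length_cm         = c("vaginal_length_cm", "vaginal_length", "vl_cm", "vl"),
  fold_lengths_mm           = c("fold_lengths_mm", "fold_lengths", "vaginal_fold_lengths_mm"),
  cumulative_fold_length_mm = c("cumulative_fold_length_mm", "cumulative_fold_length",
                                "vfl_mm", "vfl", "cumulative_vfl_mm"),
  fold_count                = c("fold_count", "n_folds", "number_of_folds"),
  maturity                  = c("maturity", "maturity_state"),
  location                  = c("location", "stranding_location")
)

#' Apply the vaginal-fold cleaning rules to a list of raw fold lengths
#'
#' A vaginal fold is any folding of the vaginal wall at least 0.5 mm long:
#' entries below 0.5 mm are dropped.  Folds measuring at least 0.5 mm but
#' less than 1 mm are rounded up to 1 mm for the cumulative length, but are
#' excluded from the fold count (only folds of at least 1 mm are counted).
#' The function is idempotent on its own `analysis_lengths` output for the
#' cumulative length.
#'
#' @param raw_lengths Numeric vector of raw fold lengths in mm (nonnegative;
#'   `NA`s are ignored).
#' @return List with `fold_count`, `cumulative_mm`, and `analysis_lengths`
#'   (the retained, rounded lengths in mm).
#' @examples
#' clean_folds(c(0.7, 2.0))  # count 1, cumulative 3 mm
#' clean_folds(0.4)          # count 0, cumulative 0 mm
#' @export
clean_folds <- function(raw_lengths) {
  raw <- raw_lengths[!is.na(raw_lengths)]
  if (any(raw < 0)) stop("fold lengths must be nonnegative", call. = FALSE)
  kept <- raw[raw >= 0.5]
  analysis <- pmax(kept, 1)
  list(fold_count = sum(kept >= 1),
       cumulative_mm = sum(analysis),
       analysis_lengths = analysis)
}

# Sniff the field separator of a delimited text file (tab vs comma).
.sniff_sep <- function(path) {
  l1 <- readLines(path, n = 1L, warn = FALSE)
  if (lengths(regmatches(l1, gregexpr("\t", l1))) >=
      lengths(regmatches(l1, gregexpr(",", l1)))) "\t" else ","
}

.num_or_stop <- function(v, col) {
  if (is.numeric(v)) return(v)
  v <- trimws(as.character(v))
  v[!nzchar(v)] <- NA
  out <- suppressWarnings(as.numeric(v))
  bad <- which(!is.na(v) & is.na(out))
  if (length(bad))
    stop("unparseable value(s) in column '", col, "', row(s) ",
         paste(head(bad, 10), collapse = ", "), call. = FALSE)
  out
}

#' Load a specimen-level measurement table
#'
#' Reads a delimited text file (comma or tab separated, sniffed from the
#' header) of one row per examined specimen.  Recognized columns (flexible
#' aliases, case-insensitive): `specimen_id`, `species` (required),
#' `body_length_cm` (required), `vaginal_length_cm`, `fold_lengths_mm`
#' (semicolon-separated list of raw fold lengths), `cumulative_fold_length_mm`,
#' `fold_count`, `maturity`, `location`.
#'
#' When a fold-length list is present, [clean_folds()] is applied per
#' specimen and its cumulative length and fold count take precedence; a
#' supplied cumulative value differing from the derived one by more than
#' 0.5 mm triggers a warning.
#'
#' @param path Path to the delimited file (decimal point `.`).
#' @param sep Field separator; `NULL` (default) sniffs comma vs tab.
#' @return A data frame of class `"specimen_records"` with canonical column
#'   names; `fold_lengths_mm` is a list-column of numeric vectors.
#' @export
load_specimens <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("specimen table not found: ", path, call. = FALSE)
  if (is.null(sep)) sep <- .sniff_sep(path)
  raw <- read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "", strip.white = TRUE)
  as_specimen_records(raw)
}

#' Normalize a raw data frame to canonical specimen records
#'
#' Applies the same column-alias resolution, type validation, fold-list
#' parsing and cleaning reconciliation as [load_specimens()], but starting
#' from an in-memory data frame.  Fold lengths may be given either as a
#' character column of semicolon-separated values or as a list-column of
#' numeric vectors.
#'
#' @param raw A data frame with recognized specimen columns.
#' @return A `"specimen_records"` data frame.
#' @export
as_specimen_records <- function(raw) {
  if (inherits(raw, "specimen_records")) return(raw)
  nm <- tolower(trimws(names(raw)))
  out <- list()
  for (canon in names(.specimen_aliases)) {
    hit <- which(nm %in% .specimen_aliases[[canon]])
    out[[canon]] <- if (length(hit)) raw[[hit[1L]]] else NULL
  }
  for (req in c("species", "body_length_cm"))
    if (is.null(out[[req]]))
      stop("mandatory column missing: ", req,
           " (accepted aliases: ", paste(.specimen_aliases[[req]], collapse = ", "),
           ")", call. = FALSE)
  nr <- nrow(raw)
  rec <- data.frame(
    specimen_id = if (!is.null(out$specimen_id)) as.character(out$specimen_id)
                  else sprintf("SP%03d", seq_len(nr)),
    species = trimws(as.character(out$species)),
    body_length_cm = .num_or_stop(out$body_length_cm, "body_length_cm"),
    stringsAsFactors = FALSE
  )
  rec$vaginal_length_cm <- if (!is.null(out$vaginal_length_cm))
    .num_or_stop(out$vaginal_length_cm, "vaginal_length_cm") else NA_real_
  rec$cumulative_fold_length_mm <- if (!is.null(out$cumulative_fold_length_mm))
    .num_or_stop(out$cumulative_fold_length_mm, "cumulative_fold_length_mm") else NA_real_
  rec$fold_count <- if (!is.null(out$fold_count))
    .num_or_stop(out$fold_count, "fold_count") else NA_real_
  rec$maturity <- if (!is.null(out$maturity))
    tolower(trimws(as.character(out$maturity))) else "unknown"
  rec$maturity[is.na(rec$maturity) | !nzchar(rec$maturity)] <- "unknown"
  rec$location <- if (!is.null(out$location)) as.character(out$location) else NA_character_

  folds <- vector("list", nr)
  if (is.list(out$fold_lengths_mm)) {
    folds <- lapply(out$fold_lengths_mm,
                    function(v) if (is.null(v) || !length(v)) NULL else as.numeric(v))
  } else if (!is.null(out$fold_lengths_mm)) {
    cells <- as.character(out$fold_lengths_mm)
    for (i in seq_len(nr)) {
      cell <- trimws(cells[i])
      if (is.na(cell) || !nzchar(cell)) next
      v <- suppressWarnings(as.numeric(trimws(strsplit(cell, ";", fixed = TRUE)[[1L]])))
      if (anyNA(v))
        stop("unparseable fold-length list in row ", i, ": '", cell, "'",
             call. = FALSE)
      folds[[i]] <- v
    }
  }
  rec$fold_lengths_mm <- I(folds)

  bad <- which(!is.na(rec$body_length_cm) & rec$body_length_cm <= 0)
  if (length(bad))
    stop("nonpositive body length in row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  bad <- which(!is.na(rec$vaginal_length_cm) & rec$vaginal_length_cm < 0)
  if (length(bad))
    stop("negative vaginal length in row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  bad <- which(vapply(folds, function(v) length(v) && any(v < 0), logical(1)))
  if (length(bad))
    stop("negative fold length in row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)

  # reconcile fold lists with cumulative / count columns
  has_list <- lengths(folds) > 0
  inconsistent <- integer(0)
  for (i in which(has_list)) {
    cf <- clean_folds(folds[[i]])
    if (!is.na(rec$cumulative_fold_length_mm[i]) &&
        abs(rec$cumulative_fold_length_mm[i] - cf$cumulative_mm) > 0.5)
      inconsistent <- c(inconsistent, i)
    rec$cumulative_fold_length_mm[i] <- cf$cumulative_mm
    rec$fold_count[i] <- cf$fold_count
  }
  if (length(inconsistent))
    warning("cumulative_fold_length_mm disagrees with the cleaned fold list ",
            "by > 0.5 mm in row(s) ", paste(inconsistent, collapse = ", "),
            "; the fold list takes precedence", call. = FALSE)
  class(rec) <- c("specimen_records", "data.frame")
  rec
}

#' Per-species arithmetic means of a specimen-level trait
#'
#' @param records A `"specimen_records"` data frame (or any data frame with a
#'   `species` column and the trait column).
#' @param traits Character vector of trait column names to average.  With a
#'   single trait, species lacking any usable value are dropped with a
#'   warning; with several traits, missing species-trait combinations are
#'   kept as `NA` so callers can subset per analysis.
#' @return A `"trait_table"`: a data frame with one row per species, the
#'   trait means, and `units`/`log_scale` attributes.
#' @export
species_means <- function(records,
                          traits = c("body_length_cm", "vaginal_length_cm",
                                     "cumulative_fold_length_mm")) {
  if (!nrow(records)) stop("empty specimen table", call. = FALSE)
  miss <- setdiff(traits, names(records))
  if (length(miss)) stop("unknown trait column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  sp <- sort(unique(records$species))
  out <- data.frame(species = sp, stringsAsFactors = FALSE)
  for (tr in traits) {
    v <- vapply(sp, function(s) {
      vals <- records[[tr]][records$species == s]
      vals <- vals[is.finite(vals)]
      if (length(vals)) mean(vals) else NA_real_
    }, numeric(1))
    out[[tr]] <- unname(v)
  }
  if (length(traits) == 1L) {
    drop <- is.na(out[[traits]])
    if (any(drop)) {
      warning("species without usable '", traits, "' values dropped: ",
              paste(out$species[drop], collapse = ", "), call. = FALSE)
      out <- out[!drop, , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  units <- setNames(ifelse(grepl("_mm$", traits), "mm",
                    ifelse(grepl("_cm$", traits), "cm", "count")), traits)
  trait_table(out, units = units,
              log_scale = setNames(rep(FALSE, length(traits)), traits))
}

#' Construct a trait table
#'
#' A light species-keyed container: a data frame with a `species` column plus
#' trait columns, carrying per-trait `units` and `log_scale` metadata as
#' attributes.
#'
#' @param df Data frame with a `species` column.
#' @param units Named character vector (per trait column).
#' @param log_scale Named logical vector (per trait column).
#' @return The data frame with class `"trait_table"`.
#' @export
trait_table <- function(df, units = NULL, log_scale = NULL) {
  if (!"species" %in% names(df)) stop("trait table needs a 'species' column", call. = FALSE)
  if (anyDuplicated(df$species)) stop("duplicate species in trait table", call. = FALSE)
  attr(df, "units") <- units
  attr(df, "log_scale") <- log_scale
  class(df) <- unique(c("trait_table", class(df)))
  df
}

#' Log10-transform the trait columns of a trait table
#'
#' @param table A `"trait_table"`.
#' @param traits Trait columns to transform (default: all non-species
#'   columns not already on log scale).
#' @return The table with the chosen columns log10-transformed, `log_scale`
#'   flags set, and units annotated as `log10(<unit>)`.
#' @export
log10_table <- function(table, traits = NULL) {
  units <- attr(table, "units")
  logs <- attr(table, "log_scale")
  if (is.null(traits)) {
    traits <- setdiff(names(table), "species")
    traits <- traits[!vapply(traits, function(tr) isTRUE(logs[[tr]]), logical(1))]
  }
  for (tr in traits) {
    v <- table[[tr]]
    bad <- which(!is.na(v) & v <= 0)
    if (length(bad))
      stop("nonpositive value(s) in trait '", tr, "' for species: ",
           paste(table$species[bad], collapse = ", "), call. = FALSE)
    table[[tr]] <- log10(v)
    if (!is.null(units) && tr %in% names(units))
      units[[tr]] <- paste0("log10(", units[[tr]], ")")
    logs[[tr]] <- TRUE
  }
  attr(table, "units") <- units
  attr(table, "log_scale") <- logs
  table
}

#' Residuals from a non-phylogenetic line fitted by sample moments
#'
#' Fits an ordinary (non-phylogenetic) RMA or OLS line of `y` on `x` using
#' sample moments and returns the vertical residuals
#' `e_i = y_i - (b0 + b1 x_i)`.  These are the inputs to residual-on-residual
#' regressions where size is first factored out of both traits.
#'
#' @param x,y Numeric vectors (log10 traits), same species order; names are
#'   carried to the result.
#' @param method `"rma"` (default) or `"ols"`.
#' @return Named numeric vector of residuals.
#' @export
nonphylo_residuals <- function(x, y, method = c("rma", "ols")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 values", call. = FALSE)
  sx <- var(x)
  if (sx <= 0) stop("zero variance in x", call. = FALSE)
  if (method == "rma") {
    sxy <- var(x, y)
    s <- sign(sxy); if (s == 0) s <- 1
    b1 <- s * sqrt(var(y) / sx)
  } else {
    b1 <- var(x, y) / sx
  }
  b0 <- mean(y) - b1 * mean(x)
  r <- y - (b0 + b1 * x)
  names(r) <- names(x)
  r
}

#' Align species labels to tree tips
#'
#' Exact string matching after whitespace trimming, with an optional
#' underscore/space fold and a user-supplied synonym map for taxonomy drift.
#'
#' @param labels Character vector of species labels.
#' @param tips Character vector of tree tip labels.
#' @param synonyms Optional named character vector mapping label -> tip.
#' @param fold_underscores Treat underscores and spaces as equivalent
#'   (default FALSE).
#' @return Character vector the length of `labels` holding the matched tip
#'   label or `NA`.
#' @export
align_species <- function(labels, tips, synonyms = NULL, fold_underscores = FALSE) {
  labels <- trimws(labels)
  tips <- trimws(tips)
  if (!is.null(synonyms)) {
    hit <- labels %in% names(synonyms)
    labels[hit] <- synonyms[labels[hit]]
  }
  key <- function(v) if (fold_underscores) gsub("[ _]+", "_", v) else v
  tips[match(key(labels), key(tips))]
}
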