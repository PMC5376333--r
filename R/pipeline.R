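# End-to-end study pipeline: specimen ingestion -> cleaning -> species means
# -> log10 -> three phylogenetic RMA regressions -> report.

#' Configuration for a scaling study run
#'
#' @param tree Path to a Newick file, or a `"phylo"` object.
#' @param specimens Path to a delimited specimen table, or a data frame in
#'   the [load_specimens()] dialect.
#' @param h Predicted scaling exponent under the dimensional null (default 1:
#'   isometry for length-on-length).
#' @param units `"mm"` (default) converts all traits to millimetres before
#'   log10 so intercepts share a unit; `"native"` keeps source units (body and
#'   vaginal length cm, fold length mm).  Slopes, correlations, lambda and
#'   all tests are unaffected by the choice.
#' @param residual_method Non-phylogenetic line used to compute the
#'   residuals entering the third regression: `"rma"` (default) or `"ols"`.
#' @param alpha Significance level for slope confidence intervals.
#' @param df Degrees-of-freedom policy for slope tests/CIs (see
#'   [slope_test()]).
#' @param r2_ss Sum-of-squares convention for R-squared (see [line_r2()]).
#' @param boundary_lrt Boundary-mixture reference for the lambda LRT.
#' @param include_fold_count_fit Also fit cumulative-fold-length residuals
#'   against log10 mean fold count (supplementary analysis; default FALSE).
#' @param synonyms Optional named character vector mapping specimen-table
#'   species names to tree tip labels.
#' @param fold_underscores Treat underscores and spaces as equivalent when
#'   matching species to tips.
#' @param out_dir Optional directory; when set, [run_study()] writes the
#'   report there.
#' @return A list of class `"study_config"`.
#' @export
study_config <- function(tree, specimens, h = 1,
                         units = c("mm", "native"),
                         residual_method = c("rma", "ols"),
                         alpha = 0.05, df = "n-2",
                         r2_ss = c("ordinary", "gls"),
                         boundary_lrt = FALSE,
                         include_fold_count_fit = FALSE,
                         synonyms = NULL, fold_underscores = FALSE,
                         out_dir = NULL) {
  if (h <= 0) stop("h must be > 0", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  structure(list(
    tree = tree, specimens = specimens, h = h,
    units = match.arg(units),
    residual_method = match.arg(residual_method),
    alpha = alpha, df = df, r2_ss = match.arg(r2_ss),
    boundary_lrt = boundary_lrt,
    include_fold_count_fit = include_fold_count_fit,
    synonyms = synonyms, fold_underscores = fold_underscores,
    out_dir = out_dir
  ), class = "study_config")
}

#' Summary statistics of a specimen table
#'
#' N, mean, sample SD (n - 1 divisor), median, min and max for vaginal
#' length (cm), cleaned cumulative vaginal fold length (mm), and fold count.
#' SD is reported as missing for single observations.
#'
#' @param records A `"specimen_records"` data frame.
#' @return A data frame of class `"specimen_summary"`, one row per variable,
#'   with attribute `sd_type = "sample"`.
#' @export
summarize_specimens <- function(records) {
  if (!nrow(records)) stop("empty specimen table", call. = FALSE)
  one <- function(v, name, unit) {
    v <- v[is.finite(v)]
    data.frame(variable = name, unit = unit, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) sd(v) else NA_real_,
               median = if (length(v)) median(v) else NA_real_,
               min = if (length(v)) min(v) else NA_real_,
               max = if (length(v)) max(v) else NA_real_,
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    one(records$vaginal_length_cm, "vaginal_length", "cm"),
    one(records$cumulative_fold_length_mm, "cumulative_fold_length", "mm"),
    one(records$fold_count, "fold_count", "count")
  )
  attr(out, "sd_type") <- "sample"
  class(out) <- c("specimen_summary", "data.frame")
  out
}

# Named log10 vector for one trait, species as names; drops NA and
# (with a warning) nonpositive values.
.log10_named <- function(values, species, trait) {
  keep <- is.finite(values)
  bad <- keep & values <= 0
  if (any(bad)) {
    warning("dropping species with nonpositive '", trait, "': ",
            paste(species[bad], collapse = ", "), call. = FALSE)
    keep <- keep & !bad
  }
  setNames(log10(values[keep]), species[keep])
}

#' Run the full scaling study
#'
#' Executes the pipeline: load and validate specimens, apply the
#' fold-cleaning rules, compute species means, align species with the tree,
#' log10-transform, then fit three phylogenetic RMA regressions: vaginal
#' length on body length, cumulative vaginal fold length on body length,
#' and (after removing body size from both traits via non-phylogenetic
#' residuals) fold-length residuals on vaginal-length residuals.
#'
#' @param config A [study_config()] object.
#' @return An object of class `"study_report"`: list with `fits` (named
#'   `"rma_fit"` objects `VL_vs_BL`, `VFL_vs_BL`, `VFLres_vs_VLres`, plus
#'   `VFLres_vs_foldcount` when enabled), `species_means` (log10 trait
#'   table used), `species_counts`, `summary`, and `provenance`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  tree <- if (inherits(config$tree, "phylo")) config$tree
          else read_phylo(config$tree)
  records <- if (is.data.frame(config$specimens)) as_specimen_records(config$specimens)
             else load_specimens(config$specimens)

  summary <- summarize_specimens(records)
  means <- species_means(records)

  matched <- align_species(means$species, tree$tip.label,
                           synonyms = config$synonyms,
                           fold_underscores = config$fold_underscores)
  if (all(is.na(matched)))
    stop("no specimen species could be matched to tree tips", call. = FALSE)
  if (anyNA(matched))
    message("species not in tree, dropped: ",
            paste(means$species[is.na(matched)], collapse = ", "))
  means <- means[!is.na(matched), , drop = FALSE]
  means$species <- matched[!is.na(matched)]

  to_mm <- config$units == "mm"
  bl <- means$body_length_cm * if (to_mm) 10 else 1
  vl <- means$vaginal_length_cm * if (to_mm) 10 else 1
  vfl <- means$cumulative_fold_length_mm
  bl_unit <- if (to_mm) "mm" else "cm"
  vl_unit <- if (to_mm) "mm" else "cm"

  log_bl <- .log10_named(bl, means$species, "body_length")
  log_vl <- .log10_named(vl, means$species, "vaginal_length")
  log_vfl <- .log10_named(vfl, means$species, "cumulative_fold_length")

  fit_args <- list(h = config$h, df = config$df, alpha = config$alpha,
                   r2_ss = config$r2_ss, boundary_lrt = config$boundary_lrt)
  fits <- list()
  fits$VL_vs_BL <- do.call(phyl_rma, c(list(tree, log_bl, log_vl), fit_args))
  fits$VFL_vs_BL <- do.call(phyl_rma, c(list(tree, log_bl, log_vfl), fit_args))

  shared <- Reduce(intersect, list(names(log_bl), names(log_vl),
                                   names(log_vfl), tree$tip.label))
  if (length(shared) < 3L)
    stop("fewer than 3 species have all of body length, vaginal length and ",
         "fold length; cannot run the residual regression", call. = FALSE)
  res_vl <- nonphylo_residuals(log_bl[shared], log_vl[shared],
                               method = config$residual_method)
  res_vfl <- nonphylo_residuals(log_bl[shared], log_vfl[shared],
                                method = config$residual_method)
  res_args <- fit_args
  res_args$h <- 1
  fits$VFLres_vs_VLres <- do.call(phyl_rma, c(list(tree, res_vl, res_vfl),
                                              res_args))
  if (isTRUE(config$include_fold_count_fit)) {
    fc <- species_means(records, "fold_count")
    fc_named <- setNames(fc$fold_count,
                         align_species(fc$species, tree$tip.label,
                                       synonyms = config$synonyms,
                                       fold_underscores = config$fold_underscores))
    log_fc <- .log10_named(unname(fc_named), names(fc_named), "fold_count")
    fits$VFLres_vs_foldcount <- do.call(phyl_rma, c(list(tree, log_fc, res_vfl),
                                                    res_args))
  }

  log_means <- trait_table(
    data.frame(species = means$species,
               log_body_length = unname(log_bl[means$species]),
               log_vaginal_length = unname(log_vl[means$species]),
               log_cumulative_fold_length = unname(log_vfl[means$species]),
               stringsAsFactors = FALSE),
    units = c(log_body_length = paste0("log10(", bl_unit, ")"),
              log_vaginal_length = paste0("log10(", vl_unit, ")"),
              log_cumulative_fold_length = "log10(mm)"),
    log_scale = c(log_body_length = TRUE, log_vaginal_length = TRUE,
                  log_cumulative_fold_length = TRUE)
  )

  digest_of <- function(x) if (is.character(x) && length(x) == 1 && file.exists(x))
    unname(md5sum(x)) else NA_character_
  report <- structure(list(
    fits = fits,
    species_means = log_means,
    species_counts = vapply(fits, function(f) f$n, integer(1)),
    summary = summary,
    provenance = list(
      package = "phylorma",
      version = as.character(utils::packageVersion("phylorma")),
      h = config$h, units = config$units,
      residual_method = config$residual_method,
      alpha = config$alpha, df_policy = config$df, r2_ss = config$r2_ss,
      boundary_lrt = config$boundary_lrt,
      tree_digest = digest_of(config$tree),
      specimens_digest = digest_of(config$specimens),
      n_specimens = nrow(records)
    )
  ), class = "study_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Flatten a study report to a scaling-table data frame
#'
#' @param x A `"study_report"`.
#' @param row.names,optional,... Data-frame method signature; unused.
#' @return One row per regression with the scaling-table column set.
#' @export
as.data.frame.study_report <- function(x, row.names = NULL, optional = FALSE, ...) {
  do.call(rbind, Map(function(f, nm) as.data.frame(f, pair = nm),
                     x$fits, names(x$fits)))
}

#' @export
print.study_report <- function(x, digits = 3, ...) {
  cat("Phylogenetic RMA scaling study (", x$provenance$n_specimens,
      " specimens)\n\n", sep = "")
  tab <- as.data.frame(x)
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(v) signif(v, digits))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Write a study report to disk
#'
#' Writes a scaling-table TSV (one row per regression), a JSON serialization
#' of the full report (lossless round trip via [read_report()]), a markdown
#' rendering of the table, and the species-mean table with a JSON unit
#' sidecar.
#'
#' @param report A `"study_report"`.
#' @param dir Output directory (created if needed).
#' @param formats Subset of `c("tsv", "json", "markdown")`.
#' @return Named character vector of written paths, invisibly.
#' @export
write_report <- function(report, dir, formats = c("tsv", "json", "markdown")) {
  formats <- match.arg(formats, several.ok = TRUE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- as.data.frame(report)
  paths <- character(0)
  if ("tsv" %in% formats) {
    p <- file.path(dir, "scaling_table.tsv")
    write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths["tsv"] <- p
    pm <- file.path(dir, "species_means.tsv")
    write.table(as.data.frame(report$species_means), pm, sep = "\t",
                quote = FALSE, row.names = FALSE)
    paths["species_means"] <- pm
    pu <- file.path(dir, "species_means_units.json")
    jsonlite::write_json(as.list(attr(report$species_means, "units")), pu,
                         auto_unbox = TRUE, pretty = TRUE)
    paths["species_means_units"] <- pu
  }
  if ("json" %in% formats) {
    p <- file.path(dir, "report.json")
    ser <- list(
      fits = lapply(report$fits, function(f)
        f[c("beta0", "beta1", "r2_corr", "r2_line", "lambda_hat",
            "lambda_identifiable", "loglik_hat", "loglik0", "ci_low",
            "ci_high", "t_stat", "df", "p_slope", "lrt_stat", "p_lambda",
            "h", "n", "alpha", "species")]),
      species_means = as.data.frame(report$species_means),
      species_counts = as.list(report$species_counts),
      summary = as.data.frame(report$summary),
      provenance = report$provenance
    )
    jsonlite::write_json(ser, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths["json"] <- p
  }
  if ("markdown" %in% formats) {
    p <- file.path(dir, "report.md")
    fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.3f", v))
    hdr <- names(tab)
    lines <- c(paste0("| ", paste(hdr, collapse = " | "), " |"),
               paste0("|", paste(rep("---", length(hdr)), collapse = "|"), "|"),
               vapply(seq_len(nrow(tab)), function(i) {
                 cells <- vapply(hdr, function(h) {
                   v <- tab[[h]][i]
                   if (is.numeric(v)) fmt(v) else as.character(v)
                 }, character(1))
                 paste0("| ", paste(cells, collapse = " | "), " |")
               }, character(1)))
    writeLines(c("# Scaling relationships", "", lines), p)
    paths["markdown"] <- p
  }
  invisible(paths)
}

#' Read back a JSON study report
#'
#' @param path Path to a `report.json` written by [write_report()].
#' @return The deserialized report list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
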