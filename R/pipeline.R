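# Orchestration: raw records -> derived phenotypes -> REML fits ->
# publication-style tables. The fitting plan mirrors the study design:
# four univariate Ucrit variants (no covariate, +SLtest, +Wtest, relative
# Ucrit), bivariate fits of absolute Ucrit against the six companion
# traits, likelihood-ratio tests of the random effects and of the genetic
# covariances. The Ucrit-DGC pair fits the hapa effect on Ucrit only; the
# HW model carries age at harvest as a covariate and the DGC model sex as
# a class variable, when those columns exist.

#' Run the full analysis pipeline
#'
#' @param config a list, or path to a YAML file, with elements:
#'   \describe{
#'     \item{phenotypes}{CSV/TSV of raw per-fish records (required).}
#'     \item{pedigree}{three-column pedigree file (required).}
#'     \item{schedule}{speed-schedule CSV; the packaged synthetic default
#'       is used when omitted.}
#'     \item{level_duration}{minutes per level (default 30).}
#'     \item{columns}{optional column mapping for the phenotype file.}
#'     \item{out_dir}{where to write tables; nothing is written when
#'       omitted.}
#'     \item{do_lrt}{fit the reduced models for likelihood ratio tests
#'       (default TRUE).}
#'     \item{seed}{echoed into provenance; the pipeline itself is
#'       deterministic.}
#'   }
#' @param quiet suppress per-stage progress messages.
#' @return An object of class \code{analysis_report}: descriptive table
#'   (\code{table1}), univariate variance components (\code{table2}),
#'   bivariate correlations (\code{table3}), \code{lrt_results}, the
#'   fitted objects, and provenance (config hash, package version, seed).
#' @export
run_analysis <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  for (field in c("phenotypes", "pedigree"))
    if (is.null(config[[field]]))
      stop("config is missing '", field, "'", call. = FALSE)
  for (field in c("phenotypes", "pedigree"))
    if (!file.exists(config[[field]]))
      stop("config ", field, " file not found: ", config[[field]],
           call. = FALSE)
  if (!is.null(config$schedule) && !file.exists(config$schedule))
    stop("config schedule file not found: ", config$schedule,
         call. = FALSE)
  say <- function(...) if (!quiet) message(...)
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- tic()
    out <- tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
    say(sprintf("stage %-12s %6.1fs", name, tic() - t0))
    out
  }

  lvl_dur <- if (is.null(config$level_duration)) 30 else
    config$level_duration
  schedule <- stage("inputs", {
    if (is.null(config$schedule)) default_speed_schedule() else
      read_speed_schedule(config$schedule, lvl_dur)
  })
  ped <- stage("pedigree", read_pedigree(config$pedigree))
  phen <- stage("phenotypes", {
    tab <- read_phenotypes(config$phenotypes, config$columns)
    derive_phenotypes(tab, schedule)
  })
  ainv <- a_inverse(ped)
  do_lrt <- !identical(config$do_lrt, FALSE)

  table1_traits <- intersect(
    c("ucrit_abs", "ucrit_rel", "agetest", "wtest", "sltest", "htest",
      "sa_test", "wstart", "hw", "dgc"), names(phen))
  table1 <- stage("table1", trait_summary(phen, table1_traits))

  uni_variants <- list(
    ucrit_abs = character(0),
    ucrit_abs_sltest = "sltest",
    ucrit_abs_wtest = "wtest",
    ucrit_rel = character(0))
  uni_response <- c("ucrit_abs", "ucrit_abs", "ucrit_abs", "ucrit_rel")
  fits_uni <- list()
  lrt_rows <- list()
  for (i in seq_along(uni_variants)) {
    vn <- names(uni_variants)[i]
    resp <- uni_response[i]
    covs <- intersect(uni_variants[[i]], names(phen))
    if (!resp %in% names(phen)) next
    fits_uni[[vn]] <- stage(vn, {
      spec <- model_spec(resp, fixed = "test_day", covariates = covs)
      bundle <- build_design(phen, spec, ped, ainv)
      fit <- reml_univariate(bundle)
      if (do_lrt) {
        red_a <- reml_univariate(bundle, random = "common_env",
                                 options = list(se = FALSE))
        red_c <- reml_univariate(bundle, random = "additive",
                                 options = list(se = FALSE))
        lrt_rows[[paste0(vn, ":additive")]] <-
          data.frame(model = vn, term = "additive",
                     as.data.frame(lrt(fit, red_a)))
        lrt_rows[[paste0(vn, ":common_env")]] <-
          data.frame(model = vn, term = "common_env",
                     as.data.frame(lrt(fit, red_c)))
      }
      fit
    })
  }
  table2 <- do.call(rbind, lapply(names(fits_uni), function(vn) {
    f <- fits_uni[[vn]]
    data.frame(model = vn, sigma_a2 = f$sigma_a2, sigma_c2 = f$sigma_c2,
               sigma_e2 = f$sigma_e2, sigma_p2 = f$sigma_p2,
               h2 = f$h2, se_h2 = f$se[["h2"]],
               c2 = f$c2, se_c2 = f$se[["c2"]],
               loglik = f$loglik, n = f$n_used,
               converged = f$converged)
  }))

  companion <- intersect(c("wtest", "sltest", "htest", "sa_test",
                           "hw", "dgc"), names(phen))
  ucrit_spec <- model_spec("ucrit_abs", fixed = "test_day")
  fits_biv <- list()
  for (tr in companion) {
    fits_biv[[tr]] <- stage(paste0("ucrit~", tr), {
      fixed2 <- if (tr == "dgc" && "sex" %in% names(phen)) "sex"
        else character(0)
      cov2 <- if (tr == "hw" && "age_harvest" %in% names(phen))
        "age_harvest" else character(0)
      random2 <- if (tr == "dgc") "additive"
        else c("additive", "common_env")
      spec2 <- model_spec(tr, fixed = fixed2, covariates = cov2,
                          random = random2)
      b1 <- build_design(phen, ucrit_spec, ped, ainv)
      b2 <- build_design(phen, spec2, ped, ainv)
      fit <- reml_bivariate(b1, b2)
      if (do_lrt) {
        red <- reml_bivariate(b1, b2, fix_ra = 0,
                              options = list(se = FALSE))
        lrt_rows[[paste0("ucrit_", tr, ":genetic_cov")]] <-
          data.frame(model = paste0("ucrit_abs:", tr),
                     term = "genetic_covariance",
                     as.data.frame(lrt(fit, red)))
      }
      fit
    })
  }
  table3 <- do.call(rbind, lapply(names(fits_biv), function(tr) {
    f <- fits_biv[[tr]]
    data.frame(trait = tr, rg = f$rg, se_rg = f$se[["rg"]],
               rp = f$rp, se_rp = f$se[["rp"]],
               rc = f$rc, re = f$re,
               h2_ucrit = f$h2[1], h2_trait = f$h2[2],
               loglik = f$loglik, n_trait = f$n_used[2],
               converged = f$converged)
  }))
  lrt_results <- if (length(lrt_rows)) do.call(rbind, lrt_rows) else NULL
  if (!is.null(lrt_results)) rownames(lrt_results) <- NULL

  # hash the analysis-relevant inputs only, so identical analyses get
  # identical provenance regardless of where the report is written
  cfg_norm <- config[setdiff(names(config), "out_dir")]
  cfg_norm <- cfg_norm[order(names(cfg_norm))]
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg_norm, tmp, auto_unbox = TRUE)
  provenance <- list(
    package_version = as.character(utils::packageVersion("swimherit")),
    config_hash = unname(tools::md5sum(tmp)),
    seed = config$seed)
  unlink(tmp)

  report <- structure(list(table1 = table1, table2 = table2,
                           table3 = table3, lrt_results = lrt_results,
                           fits_univariate = fits_uni,
                           fits_bivariate = fits_biv,
                           provenance = provenance),
                      class = "analysis_report")
  if (!is.null(config$out_dir))
    write_report(report, config$out_dir)
  report
}

#' Write an analysis report to disk
#'
#' Emits \code{table1.csv}, \code{table2.csv}, \code{table3.csv},
#' \code{lrt_tests.csv}, a JSON summary and a markdown report. Outputs are
#' deterministic for a given input (no timestamps), so reruns are
#' byte-identical. Partial files are removed if any write fails.
#'
#' @param report an \code{analysis_report}.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("table1.csv", "table2.csv", "table3.csv",
                                "lrt_tests.csv", "report.json",
                                "report.md"))
  ok <- FALSE
  on.exit(if (!ok) unlink(paths))
  utils::write.csv(report$table1, paths[1], row.names = FALSE)
  utils::write.csv(report$table2, paths[2], row.names = FALSE)
  utils::write.csv(report$table3, paths[3], row.names = FALSE)
  if (!is.null(report$lrt_results))
    utils::write.csv(report$lrt_results, paths[4], row.names = FALSE)
  jsonlite::write_json(list(table1 = report$table1,
                            table2 = report$table2,
                            table3 = report$table3,
                            lrt = report$lrt_results,
                            provenance = report$provenance),
                       paths[5], auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  md <- c("# Swimming-performance genetic analysis", "",
          "## Descriptive statistics", md_table(report$table1), "",
          "## Variance components (univariate Ucrit models)",
          md_table(report$table2), "",
          "## Genetic and phenotypic correlations with absolute Ucrit",
          md_table(report$table3), "")
  if (!is.null(report$lrt_results))
    md <- c(md, "## Likelihood ratio tests",
            md_table(report$lrt_results), "")
  md <- c(md, paste0("_package version ",
                     report$provenance$package_version,
                     ", config hash ", report$provenance$config_hash,
                     "_"))
  writeLines(md, paths[6])
  ok <- TRUE
  invisible(paths)
}

md_table <- function(df) {
  fmt <- vapply(df, function(col) {
    if (is.numeric(col)) formatC(col, format = "g", digits = 4)
    else as.character(col)
  }, character(nrow(df)))
  if (nrow(df) == 1L) fmt <- matrix(fmt, nrow = 1L)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(fmt, 1L, function(r)
    paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}

#' @method print analysis_report
#' @export
print.analysis_report <- function(x, ...) {
  cat("Analysis report:", nrow(x$table2), "univariate and",
      nrow(x$table3), "bivariate fits\n")
  cat("package", x$provenance$package_version, " config hash",
      x$provenance$config_hash, "\n")
  invisible(x)
}

#' Standardised selection intensity
#'
#' Mean deviation (in phenotypic SDs) of the selected group when the top
#' \code{p} proportion of a normal distribution is kept:
#' \eqn{i = \phi(z_p)/p}.
#'
#' @param p selected proportion, in (0, 1).
#' @return Selection intensity.
#' @examples
#' selection_intensity(0.10)  # 1.755
#' @export
selection_intensity <- function(p) {
  if (any(p <= 0 | p >= 1))
    stop("selected proportion must be in (0, 1)", call. = FALSE)
  stats::dnorm(stats::qnorm(1 - p)) / p
}

#' Correlated response to selection
#'
#' Breeder's-equation calculator for indirect selection: selecting the top
#' \code{p} proportion on trait x changes trait y by
#' \deqn{CR_y = i\, r_g\, h_x h_y\, \sigma_{P(y)}}
#' per generation, against a direct response \eqn{R_y = i\, h_y^2
#' \sigma_{P(y)}}. The ratio \eqn{r_g h_x / h_y} is the relative
#' efficiency of indirect selection. All inputs must be supplied; nothing
#' is inferred from fitted objects, so gaps in reported parameters are
#' explicit.
#'
#' @param selected_proportion proportion kept, in (0, 1).
#' @param h2_x,h2_y heritabilities of the selection and response traits.
#' @param rg genetic correlation between the traits.
#' @param sd_py phenotypic SD of the response trait (its units).
#' @return list with \code{selection_intensity},
#'   \code{correlated_response}, \code{direct_response} and
#'   \code{relative_efficiency}.
#' @export
predict_correlated_response <- function(selected_proportion, h2_x, h2_y,
                                        rg, sd_py) {
  stopifnot(h2_x >= 0, h2_x <= 1, h2_y >= 0, h2_y <= 1,
            rg >= -1, rg <= 1, sd_py >= 0)
  i <- selection_intensity(selected_proportion)
  cr <- i * rg * sqrt(h2_x) * sqrt(h2_y) * sd_py
  dr <- i * h2_y * sd_py
  list(selection_intensity = i, correlated_response = cr,
       direct_response = dr,
       relative_efficiency = if (dr > 0) cr / dr else NA_real_)
}
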