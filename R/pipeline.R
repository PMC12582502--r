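# File-based pipeline stages tying the modules into reproducible runs. Each
# stage reads/writes delimited text or JSON and records a manifest with the
# configuration, seed and package version, so any artifact can be
# regenerated from its manifest. A thin command-line wrapper around
# run_pipeline() lives in inst/cli/bmdd.

#' @noRd
write_manifest <- function(out_dir, stage, cfg) {
  manifest <- list(stage = stage, config = cfg,
                   package_version = as.character(packageVersion("bmdd")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Run a file-based pipeline stage
#'
#' Executes one stage of the simulate / preprocess / fit / impute / sample /
#' ppc / evaluate / daa / daa-null workflow against files on disk. Identical
#' configuration and seed reproduce byte-identical numeric outputs; every
#' stage writes `manifest.json` next to its outputs.
#'
#' @param stage stage name (see Details).
#' @param config named list of stage parameters (paths, seed, module
#'   options). Common keys: `counts` (input table), `out_dir` (output
#'   directory, created if absent), `seed`, `transpose`.
#' @details Stages and their main keys:
#' * `simulate`: `generator` (`"bmdd"`, `"gamma"`, `"lognormal"`,
#'   `"poisson"`, `"negbin"`), `n`, `m`, `seed`, plus generator options;
#'   writes `counts.tsv`, `truth_composition.tsv`, `truth.json`.
#' * `preprocess`: `counts`, `min_depth`, `min_prevalence`, `winsor_q`;
#'   writes `counts.tsv`.
#' * `fit`: `counts`, `max_iter`, `rel_tol`, `seed`; writes `fit.json`.
#' * `impute`: `counts`, `method` (`"bmdd"` needs `fit`, else
#'   `"naive1".."naive4"`); writes `composition.tsv`.
#' * `sample`: `fit`, `L`, `seed`; writes `sample_<l>.tsv` and
#'   `samples.json`.
#' * `ppc`: `fit`, `counts`, `L`, `seed`; writes `ppc_summary.tsv`.
#' * `evaluate`: `estimate`, `truth` (composition tables); writes
#'   `metrics.tsv`.
#' * `daa`: `counts` + `metadata` (TSV with `sample_id`, `group`) or
#'   precomputed samples via `fit`; `L`, `combine`, `alpha`, `seed`; writes
#'   `daa.tsv`.
#' * `daa-null`: as `daa` plus `reps`; writes `fdr_curve.tsv`.
#' @return the stage's main in-memory result, invisibly.
#' @export
run_pipeline <- function(stage = c("simulate", "preprocess", "fit", "impute",
                                   "sample", "ppc", "evaluate", "daa",
                                   "daa-null"),
                         config = list()) {
  stage <- match.arg(stage)
  cfg <- config
  out_dir <- cfg$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed %||% 1L)
  transpose <- isTRUE(cfg$transpose)
  get_counts <- function() read_count_table(cfg$counts, transpose = transpose)

  result <- switch(stage,
    simulate = {
      gen <- cfg$generator %||% "bmdd"
      sim <- if (gen == "bmdd") {
        hp <- if (!is.null(cfg$hyperparams)) {
          cfg$hyperparams
        } else {
          random_hyperparams(cfg$m, seed = seed)
        }
        simulate_bmdd(hp, n = cfg$n, depths = cfg$depths, seed = seed)
      } else if (!is.null(cfg$prop_differential)) {
        simulate_daa(gen, n = cfg$n, m = cfg$m,
                     prop_differential = cfg$prop_differential,
                     effect_fold = cfg$effect_fold %||% 10,
                     depths = cfg$depths,
                     correlation = cfg$correlation %||%
                       list(structure = "none", rho = 0),
                     params = cfg$params %||% list(), seed = seed)
      } else {
        simulate_parametric(gen, n = cfg$n, m = cfg$m, depths = cfg$depths,
                            correlation = cfg$correlation %||%
                              list(structure = "none", rho = 0),
                            params = cfg$params %||% list(), seed = seed)
      }
      write_count_table(sim$counts, file.path(out_dir, "counts.tsv"))
      write_count_table(sim$truth$composition,
                        file.path(out_dir, "truth_composition.tsv"))
      truth_meta <- sim$truth[setdiff(names(sim$truth),
                                      c("composition", "latent"))]
      jsonlite::write_json(truth_meta, file.path(out_dir, "truth.json"),
                           auto_unbox = TRUE, digits = NA)
      sim
    },
    preprocess = {
      W <- preprocess_counts(get_counts(),
                             min_depth = cfg$min_depth %||% 1000L,
                             min_prevalence = cfg$min_prevalence %||% 0.2,
                             winsor_q = cfg$winsor_q %||% 0.97)
      write_count_table(W, file.path(out_dir, "counts.tsv"))
      W
    },
    fit = {
      fit <- bmdd_fit(get_counts(),
                      bmdd_config(max_iter = cfg$max_iter %||% 200L,
                                  rel_tol = cfg$rel_tol %||% 1e-6,
                                  seed = seed))
      write_bmdd_fit(fit, file.path(out_dir, "fit.json"))
      fit
    },
    impute = {
      method <- cfg$method %||% "bmdd"
      X <- if (method == "bmdd") {
        posterior_mean(read_bmdd_fit(cfg$fit))
      } else {
        naive_impute(get_counts(), method)
      }
      write_count_table(X, file.path(out_dir, "composition.tsv"))
      X
    },
    sample = {
      fit <- read_bmdd_fit(cfg$fit)
      S <- posterior_sample(fit, L = cfg$L %||% 100L, seed = seed)
      for (l in seq_len(S$L)) {
        write_count_table(S$samples[[l]],
                          file.path(out_dir, sprintf("sample_%03d.tsv", l)))
      }
      jsonlite::write_json(list(L = S$L, seed = S$seed,
                                files = sprintf("sample_%03d.tsv",
                                                seq_len(S$L))),
                           file.path(out_dir, "samples.json"),
                           auto_unbox = TRUE)
      S
    },
    ppc = {
      fit <- read_bmdd_fit(cfg$fit)
      ppc <- posterior_predict(fit, get_counts(), L = cfg$L %||% 200L,
                               seed = seed)
      write.table(ppc$summary, file.path(out_dir, "ppc_summary.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      ppc
    },
    evaluate = {
      est <- read_composition_table(cfg$estimate)
      truth <- read_composition_table(cfg$truth)
      rep <- evaluate_composition(est, truth)
      write.table(as.data.frame(rep), file.path(out_dir, "metrics.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      rep
    },
    `daa` = ,
    `daa-null` = {
      W <- get_counts()
      meta <- read.table(cfg$metadata, header = TRUE, sep = "\t")
      group <- meta$group[match(rownames(W), meta$sample_id)]
      if (anyNA(group)) stop("metadata is missing sample ids", call. = FALSE)
      fit <- if (!is.null(cfg$fit)) {
        read_bmdd_fit(cfg$fit)
      } else {
        bmdd_fit(W, bmdd_config(max_iter = cfg$max_iter %||% 50L,
                                seed = seed))
      }
      S <- posterior_sample(fit, L = cfg$L %||% 100L, seed = seed + 1L)
      combine <- cfg$combine %||% "rubin"
      if (stage == "daa") {
        res <- daa_multiple(S, group, combine = combine,
                            alpha = cfg$alpha %||% 0.05)
        write.table(res, file.path(out_dir, "daa.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        res
      } else {
        curve <- shuffled_fdr(
          function(gp, a) daa_multiple(S, gp, combine = combine, alpha = a),
          group, reps = cfg$reps %||% 100L, seed = seed + 2L)
        write.table(curve, file.path(out_dir, "fdr_curve.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        curve
      }
    }
  )
  write_manifest(out_dir, stage,
                 cfg[vapply(cfg, function(x)
                   is.atomic(x) && length(x) < 100, logical(1))])
  invisible(result)
}
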