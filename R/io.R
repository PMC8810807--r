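#' @title Result tables, subject-table loading and the command-line front end
#' @name workbench-io
NULL

#' Write an MI table and its dissimilarity matrices to CSV
#'
#' @param mi An `mi_table`.
#' @param path Output CSV path for the summary.
#' @return `path`, invisibly.
#' @export
write_mi_csv <- function(mi, path) {
  summ <- if (inherits(mi, "mi_table")) mi$summary else tibble::as_tibble(mi)
  readr::write_csv(summ, path)
  invisible(path)
}

#' Write a dissimilarity matrix as dense CSV
#'
#' Header row is the time index (`t1..tT`).
#'
#' @param m Numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  df <- as.data.frame(m)
  names(df) <- paste0("t", seq_len(ncol(m)))
  readr::write_csv(df, path)
  invisible(path)
}

#' Load a subject accuracy table from CSV
#'
#' Applies an optional column mapping (target = source) so deposited source
#' data with different column names can be adapted without editing the file,
#' then validates the schema.
#'
#' @param path CSV path.
#' @param mapping Named character vector or list mapping the schema columns
#'   (`subject_id`, `experiment`, `sequence_id`, `condition`, `pair_type`,
#'   `n_trials`, `n_correct` or `correct`) to the file's column names.
#' @return A validated subject accuracy tibble.
#' @export
read_subject_table <- function(path, mapping = NULL) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  if (!is.null(mapping)) {
    for (target in names(mapping)) {
      src <- mapping[[target]]
      if (!src %in% names(tab)) {
        stop(sprintf("mapping: source column `%s` not in %s", src, path),
             call. = FALSE)
      }
      names(tab)[names(tab) == src] <- target
    }
  }
  if (!"subject_id" %in% names(tab)) {
    stop(sprintf("%s: no `subject_id` column after mapping", path),
         call. = FALSE)
  }
  has_counts <- all(c("n_trials", "n_correct") %in% names(tab))
  if (!has_counts && !"correct" %in% names(tab)) {
    stop(sprintf("%s: need `n_trials`/`n_correct` or `correct`", path),
         call. = FALSE)
  }
  if (has_counts && any(tab$n_correct < 0 | tab$n_correct > tab$n_trials)) {
    stop(sprintf("%s: `n_correct` outside [0, n_trials]", path),
         call. = FALSE)
  }
  tab
}

parse_cli_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) {
      stop(sprintf("unexpected argument `%s`", a), call. = FALSE)
    }
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      flags[[key]] <- TRUE
      i <- i + 1L
    } else {
      flags[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  flags
}

parse_grid <- function(spec) {
  parts <- as.numeric(strsplit(spec, ":", fixed = TRUE)[[1]])
  if (length(parts) != 3L || anyNA(parts)) {
    stop(sprintf("grid spec `%s` must be from:to:step", spec), call. = FALSE)
  }
  seq(parts[1], parts[2], by = parts[3])
}

flag_num <- function(flags, key, default) {
  if (is.null(flags[[key]])) default else as.numeric(flags[[key]])
}

flag_chr <- function(flags, key, default) {
  if (is.null(flags[[key]])) default else as.character(flags[[key]])
}

write_run_log <- function(dir, subcommand, flags, seed) {
  lines <- c(
    sprintf("time: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    sprintf("package: contextreset %s",
            as.character(utils::packageVersion("contextreset"))),
    sprintf("subcommand: %s", subcommand),
    sprintf("seed: %d", seed),
    sprintf("config: %s", paste(sprintf("%s=%s", names(flags),
                                        vapply(flags, as.character,
                                               character(1))),
                                collapse = " "))
  )
  writeLines(lines, file.path(dir, "run.log"))
}

#' Command-line front end
#'
#' Thin dispatcher over the package functions, intended to be driven by the
#' `inst/cli/contextreset` Rscript wrapper. Subcommands:
#'
#' * `simulate --experiment N [--condition C] [--p --lam --features --iters
#'   --seed --reference --out-dir]` — MI summary CSV plus the Monte-Carlo
#'   average dissimilarity matrix per condition.
#' * `sweep --p-grid a:b:s --lam-grid a:b:s [--iters --seed --margin
#'   --reference --behav --out-dir]` — one CSV row per grid cell.
#' * `fit [--behav means.csv] [--p --lam --iters --seed]` — GLM and GLMM of
#'   behavioural group means on suite MI (synthetic means when no file is
#'   given).
#' * `stats --experiment N [--table subjects.csv | --preset name] [--seed]`
#'   — the experiment's ANOVA + contrast battery.
#' * `synth --preset name [--seed --out-dir]` — synthetic subject table.
#' * `validate --design file.json [--strict]` — design check; non-zero exit
#'   when violations are found.
#'
#' Every run writes `run.log` (config echo, seed, package version) to the
#' output directory.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status, invisibly (0 on success).
#' @export
tom_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0L) {
      stop("usage: contextreset <simulate|sweep|fit|stats|synth|validate> [--flags]",
           call. = FALSE)
    }
    sub <- args[1]
    flags <- parse_cli_flags(args[-1])
    out_dir <- flag_chr(flags, "out-dir", ".")
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    seed <- as.integer(flag_num(flags, "seed", 1))
    params <- model_params(
      n_features = flag_num(flags, "features", 100),
      p = flag_num(flags, "p", 0.02),
      lam = flag_num(flags, "lam", 0.2),
      n_iter = flag_num(flags, "iters", 1000))
    reference <- flag_chr(flags, "reference", "first")

    if (sub == "simulate") {
      designs <- builtin_designs()
      if (!is.null(flags[["experiment"]])) {
        exp_id <- as.integer(flag_num(flags, "experiment", NA))
        designs <- Filter(function(d) d$experiment == exp_id, designs)
        if (!is.null(flags[["condition"]])) {
          designs <- list(builtin_design(exp_id, flags[["condition"]]))
          names(designs) <- designs[[1]]$name
        }
      }
      set.seed(seed)
      tables <- lapply(designs, simulate_condition, params = params,
                       reference = reference, seed = NULL)
      mi <- bind_mi_tables(tables)
      write_mi_csv(mi, file.path(out_dir, "mi_table.csv"))
      for (d in designs) {
        m <- average_dissimilarity(d, params, seed = NULL)
        write_matrix_csv(m, file.path(out_dir,
                                      sprintf("dissimilarity_%s.csv", d$name)))
      }
      write_run_log(out_dir, sub, flags, seed)
    } else if (sub == "sweep") {
      p_grid <- parse_grid(flag_chr(flags, "p-grid", "0.01:0.4:0.01"))
      lam_grid <- parse_grid(flag_chr(flags, "lam-grid", "0.05:1:0.01"))
      behav <- if (!is.null(flags[["behav"]])) {
        readr::read_csv(flags[["behav"]], show_col_types = FALSE)
      } else NULL
      grid <- parameter_sweep(p_grid, lam_grid, params, reference,
                              behav = behav,
                              margin = flag_num(flags, "margin", 2),
                              seed = seed)
      readr::write_csv(tibble::as_tibble(grid), file.path(out_dir, "sweep.csv"))
      write_run_log(out_dir, sub, flags, seed)
    } else if (sub == "fit") {
      behav <- if (!is.null(flags[["behav"]])) {
        readr::read_csv(flags[["behav"]], show_col_types = FALSE)
      } else {
        synthetic_behaviour_means(seed = seed)
      }
      mi <- run_experiment_suite(params, reference, seed = seed)
      g <- fit_glm(behav, mi)
      m <- fit_glmm(behav, mi)
      fit_tbl <- tibble::tibble(
        method = c("glm", "glmm"), r2 = c(g$r2, m$r2),
        p_value = c(g$p_value, m$p_value),
        intercept = c(g$coefficients[1], m$coefficients[1]),
        slope = c(g$coefficients[2], m$coefficients[2]))
      readr::write_csv(fit_tbl, file.path(out_dir, "fit.csv"))
      write_run_log(out_dir, sub, flags, seed)
      print(fit_tbl)
    } else if (sub == "stats") {
      exp_id <- as.integer(flag_num(flags, "experiment", 1))
      table <- if (!is.null(flags[["table"]])) {
        read_subject_table(flags[["table"]])
      } else {
        generate_subjects(effect_config(flag_chr(flags, "preset",
                                                 paste0("exp", exp_id))),
                          seed = seed)
      }
      res <- experiment_stats(table, exp_id)
      readr::write_csv(res$anova, file.path(out_dir, "stats_anova.csv"))
      readr::write_csv(res$contrasts,
                       file.path(out_dir, "stats_contrasts.csv"))
      write_run_log(out_dir, sub, flags, seed)
    } else if (sub == "synth") {
      config <- effect_config(flag_chr(flags, "preset", "exp1"))
      tab <- generate_subjects(config, seed = seed)
      readr::write_csv(tab, file.path(out_dir, "subjects.csv"))
      write_run_log(out_dir, sub, flags, seed)
    } else if (sub == "validate") {
      if (is.null(flags[["design"]])) {
        stop("validate requires --design <file.json>", call. = FALSE)
      }
      design <- read_design(flags[["design"]])
      v <- validate_design(design, strict = isTRUE(flags[["strict"]]) ||
                             identical(flags[["strict"]], "true"))
      if (length(v) > 0L) {
        message(paste(v, collapse = "\n"))
        return(invisible(1L))
      }
      message(sprintf("%s: design valid", design$name))
    } else {
      stop(sprintf("unknown subcommand `%s`", sub), call. = FALSE)
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
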