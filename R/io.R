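#' Write a functional covariate table in wide CSV format
#'
#' One row per subject, header `id, t_<g1>, t_<g2>, ...` with the grid
#' encoded in the column names.
#'
#' @param functional A [functional_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_functional_csv <- function(functional, path) {
  stopifnot(inherits(functional, "functional_dataset"))
  df <- tibble::as_tibble(functional$values, .name_repair = "minimal")
  names(df) <- paste0("t_", format(functional$grid, digits = 15, trim = TRUE))
  df <- dplyr::bind_cols(tibble::tibble(id = functional$subject_ids), df)
  readr::write_csv(df, path)
  invisible(path)
}

#' Read a functional covariate table in wide CSV format
#'
#' @param path CSV path with header `id, t_<g1>, ...`.
#' @return A [functional_dataset()].
#' @export
read_functional_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"id" %in% names(df)) stop_input("functional table must have an 'id' column")
  tcols <- grep("^t_", names(df), value = TRUE)
  if (length(tcols) < 4L) stop_input("functional table needs at least 4 't_' columns")
  grid <- as.numeric(sub("^t_", "", tcols))
  if (anyNA(grid)) stop_input("could not parse grid values from the header")
  o <- order(grid)
  functional_dataset(as.matrix(df[tcols[o]]), grid[o], subject_ids = df$id)
}

#' Read a dataset bundle from scalar and functional CSV files
#'
#' The scalar table must have columns `id`, `time`, `event` plus covariate
#' columns named by role prefix (`V1, V2, ...` fixed coefficients; `Z1,
#' Z2, ...` varying coefficients; `U` index variable). The functional table
#' is wide-format (see [read_functional_csv()]) and is re-aligned to the
#' scalar table by `id`.
#'
#' @param scalar_path CSV path of the per-subject table.
#' @param functional_path Optional CSV path of the functional covariate.
#' @return A list of class `dataset_bundle` with `data` (tibble) and
#'   `functional` (a [functional_dataset()] or `NULL`).
#' @export
read_bundle <- function(scalar_path, functional_path = NULL) {
  if (!file.exists(scalar_path)) stop_input("file not found: ", scalar_path)
  data <- readr::read_csv(scalar_path, show_col_types = FALSE, progress = FALSE)
  for (col in c("id", "time", "event")) {
    if (!col %in% names(data)) {
      stop_input("scalar table is missing the '", col, "' column")
    }
  }
  bad_ev <- which(!data$event %in% c(0, 1))
  if (length(bad_ev) > 0L) {
    stop_input(
      "event must be 0/1; offending row(s): ",
      paste(utils::head(bad_ev, 5L), collapse = ", ")
    )
  }
  num_cols <- setdiff(names(data), "id")
  for (col in num_cols) {
    bad <- which(!is.finite(as.numeric(data[[col]])))
    if (length(bad) > 0L) {
      stop_input(
        "non-numeric or missing value in column '", col,
        "', row(s): ", paste(utils::head(bad, 5L), collapse = ", ")
      )
    }
  }
  functional <- NULL
  if (!is.null(functional_path)) {
    if (!file.exists(functional_path)) {
      stop_input("file not found: ", functional_path)
    }
    functional <- read_functional_csv(functional_path)
    pos <- match(data$id, functional$subject_ids)
    if (anyNA(pos) || length(functional$subject_ids) != nrow(data)) {
      stop_input("ids of scalar and functional tables do not match 1-1")
    }
    functional <- functional_dataset(
      functional$values[pos, , drop = FALSE],
      functional$grid,
      subject_ids = functional$subject_ids[pos]
    )
  }
  structure(list(data = data, functional = functional), class = "dataset_bundle")
}

#' Write a dataset bundle (and optional simulation truth) to disk
#'
#' @param x An `fvc_sim` from [simulate_dataset()] or a `dataset_bundle`.
#' @param scalar_path Output CSV path for the per-subject table.
#' @param functional_path Optional output CSV path for the curves.
#' @param truth_path Optional output JSON path for the generating
#'   parameters (simulations only).
#' @return `scalar_path`, invisibly.
#' @export
write_bundle <- function(x, scalar_path, functional_path = NULL,
                         truth_path = NULL) {
  data <- x$data
  readr::write_csv(data, scalar_path)
  if (!is.null(functional_path) && !is.null(x$functional)) {
    write_functional_csv(x$functional, functional_path)
  }
  if (!is.null(truth_path) && !is.null(x$truth)) {
    tr <- x$truth
    jsonlite::write_json(
      list(
        theta0 = tr$theta0, eta0 = tr$eta0,
        censor_bound = tr$censor_bound, seed = tr$seed
      ),
      truth_path,
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(scalar_path)
}

#' Serialize a fitted model as a JSON report
#'
#' Writes blocks, estimates, standard errors, log partial likelihood, both
#' AIC flavours and convergence metadata. Deterministic: identical fits
#' produce byte-identical reports.
#'
#' @param fit An `fvc_cox_fit`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "fvc_cox_fit"))
  co <- tidy(fit)
  report <- list(
    package_version = as.character(utils::packageVersion("fvcox")),
    n = fit$n, n_events = fit$n_events, m = fit$m,
    spline = if (is.null(fit$spec)) {
      NULL
    } else {
      list(
        n_interior_knots = fit$spec$n_interior_knots,
        order = fit$spec$order, domain = fit$spec$domain,
        basis_dim = fit$spec$basis_dim
      )
    },
    terms = lapply(seq_len(nrow(co)), function(i) {
      list(
        term = co$term[i], block = co$block[i],
        estimate = co$estimate[i], se = co$std.error[i]
      )
    }),
    loglik = fit$loglik, aic = fit$aic, aic_full = fit$aic_full,
    n_iter = fit$n_iter, converged = fit$converged,
    monotone_likelihood = fit$monotone_likelihood
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Materialize a test fixture on disk
#'
#' `kind = "tiny-worked"` writes a fixed, hand-checkable 3-subject dataset
#' (one fixed-coefficient covariate, one varying-coefficient covariate, a
#' 5-point functional curve each; byte-stable across runs). `kind =
#' "simulation"` writes a seeded draw from the study design.
#'
#' @param kind `"tiny-worked"` or `"simulation"`.
#' @param seed Seed for the simulation fixture.
#' @param dir Output directory (created if missing).
#' @param n,censor_rate Size and censoring target of the simulation fixture.
#' @return Named list of written paths, invisibly.
#' @export
make_fixture <- function(kind = c("tiny-worked", "simulation"), seed = 7L,
                         dir = tempdir(), n = 60L, censor_rate = 0.3) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scalar_path <- file.path(dir, paste0(kind, "-scalar.csv"))
  func_path <- file.path(dir, paste0(kind, "-functional.csv"))
  if (kind == "tiny-worked") {
    fx <- tiny_worked_fixture()
    write_bundle(fx, scalar_path, func_path)
    paths <- list(scalar = scalar_path, functional = func_path)
  } else {
    sim <- simulate_dataset(sim_config(n = n, censor_rate = censor_rate, seed = seed))
    truth_path <- file.path(dir, paste0(kind, "-truth.json"))
    write_bundle(sim, scalar_path, func_path, truth_path)
    paths <- list(
      scalar = scalar_path, functional = func_path, truth = truth_path
    )
  }
  invisible(paths)
}

# Fixed 3-subject dataset used in hand computations: V1 fixed covariate,
# Z1 varying covariate with index U in {0, 0.5, 1}, all events, distinct
# times, curves proportional to the leading eigenfunction so the first
# score is hand-computable.
tiny_worked_fixture <- function() {
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  phi1 <- true_eigenfunction(1L, grid)
  curves <- rbind(0.5 * phi1, -1 * phi1, 2 * phi1)
  fd <- functional_dataset(curves, grid, subject_ids = 1:3)
  data <- tibble::tibble(
    id = 1:3,
    time = c(3, 1, 2),
    event = c(1L, 1L, 1L),
    V1 = c(0.5, -0.2, 1.0),
    Z1 = c(1, 2, -1),
    U = c(0, 0.5, 1)
  )
  list(data = data, functional = fd)
}
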