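# Parameter fitting of NCI and fold-change time courses: relative-distance
# objective, Metropolis exploration in log10-parameter space, and
# Levenberg-Marquardt refinement.

#' Relative distance between two non-negative series
#'
#' \code{d = (1/N) * sum_k |X_k - x_k| / max(X_k, x_k)}: the average
#' relative error per timepoint. Terms with \code{X_k = x_k = 0} contribute
#' zero (0/0 convention, needed e.g. for pre-stimulus fold-change points
#' normalized to baseline).
#'
#' @param X observed series (non-negative).
#' @param x model series (non-negative, same length).
#' @return the distance (>= 0; 0 iff the series are identical).
#' @export
fit_distance <- function(X, x) {
  if (length(X) != length(x)) stop("series must have equal length")
  if (length(X) < 1) stop("need at least one timepoint")
  if (any(X < 0) || any(x < 0)) stop("series must be non-negative")
  den <- pmax(X, x)
  num <- abs(X - x)
  terms <- ifelse(den > 0, num / den, 0)
  mean(terms)
}

#' Model NCI series at requested times
#'
#' @param params a [kinetic_params()] set.
#' @param forcing a [forcing_signal()].
#' @param times sampling times (min).
#' @param area_ratio nuclear-to-total area ratio (default 1/3).
#' @return numeric NCI series.
#' @export
model_nci_series <- function(params, forcing, times, area_ratio = 1 / 3) {
  traj <- simulate_nfkb(params, forcing, t_grid = times,
                        area_ratio = area_ratio)
  as.numeric(traj$nci)
}

#' Model fold-change series for a regulated gene
#'
#' Mature-mRNA fold change \code{R(t)/R(0)} of a gene under the control of
#' nuclear NF-kB, with \code{R(0)} the pre-stimulus resting level. A
#' defined baseline requires basal gene activation (\code{k_on0_G > 0}).
#'
#' @param params a [kinetic_params()] set.
#' @param gene a [gene_params()] set.
#' @param forcing a [forcing_signal()].
#' @param times sampling times (min).
#' @param eps smallest admissible baseline \code{R(0)}.
#' @return numeric fold-change series.
#' @export
fold_change_series <- function(params, gene, forcing, times, eps = 1e-6) {
  genes <- list(g = gene)
  traj <- simulate_nfkb(params, forcing, genes = genes, t_grid = times)
  R <- traj$states[, "gene_g_R"]
  R0 <- resting_state(params, genes)["gene_g_R"]
  if (R0 <= eps)
    stop("baseline R(0) is ~0; the gene needs basal activation (k_on0_G > 0) ",
         "for a defined fold change")
  as.numeric(R / R0)
}

#' Define a fitting problem
#'
#' Bundles observed datasets with the model structure and the free
#' parameters. Each dataset is either a population NCI series or a per-gene
#' fold-change series; all are compared with the model through
#' [fit_distance()] and the per-dataset distances are summed.
#'
#' @param datasets list of datasets, each a list with \code{kind}
#'   (\code{"nci"} or \code{"fold_change"}), \code{times} (min),
#'   \code{values} (non-negative), and for fold-change datasets
#'   \code{gene} (the id of the gene it constrains).
#' @param params initial [kinetic_params()] (the shared dynamics set).
#' @param genes named list of initial [gene_params()], one per fitted gene.
#' @param free_nfkb character vector of free kinetic parameter names.
#' @param free_genes named list: for each gene id, the free gene-parameter
#'   names.
#' @param degrees per-parameter uncertainty degrees bounding the search
#'   (log10 half-widths); defaults to [default_degrees()] for kinetic
#'   parameters.
#' @param gene_degree log10 half-width of the search box for free gene
#'   parameters (default 1.5: expression kinetics are the least constrained
#'   part of the model and fitted degradation rates span orders of
#'   magnitude).
#' @param area_ratio NCI area ratio.
#' @return an object of class \code{fit_problem}.
#' @export
fit_problem <- function(datasets, params, genes = list(),
                        free_nfkb = character(0), free_genes = list(),
                        degrees = default_degrees(), gene_degree = 1.5,
                        area_ratio = 1 / 3) {
  if (!length(datasets)) stop("need at least one dataset")
  for (ds in datasets) {
    if (!ds$kind %in% c("nci", "fold_change")) stop("unknown dataset kind")
    if (!length(ds$values)) stop("empty dataset")
    if (length(ds$times) != length(ds$values)) stop("times/values mismatch")
    if (any(ds$values < 0)) stop("observed values must be non-negative")
    if (stats::sd(ds$values) == 0) stop("degenerate (zero-variance) dataset")
    if (ds$kind == "fold_change" && is.null(genes[[ds$gene]]))
      stop("fold-change dataset references unknown gene ", ds$gene)
  }
  bad <- setdiff(free_nfkb, .kinetic_names)
  if (length(bad)) stop("unknown free parameter(s): ", paste(bad, collapse = ", "))
  # assemble the free-parameter table: name, scope, initial, degree
  tab <- NULL
  for (nm in free_nfkb) {
    D <- if (nm %in% names(degrees)) degrees[[nm]] else 1
    tab <- rbind(tab, data.frame(scope = "nfkb", gene = NA, name = nm,
                                 init = params[[nm]], degree = D))
  }
  for (gid in names(free_genes)) {
    for (nm in free_genes[[gid]]) {
      tab <- rbind(tab, data.frame(scope = "gene", gene = gid, name = nm,
                                   init = genes[[gid]][[nm]],
                                   degree = gene_degree))
    }
  }
  if (is.null(tab) || !nrow(tab)) stop("no free parameters")
  if (any(tab$init <= 0))
    stop("free parameters must be strictly positive to fit on a log scale")
  structure(list(datasets = datasets, params = params, genes = genes,
                 free = tab, area_ratio = area_ratio), class = "fit_problem")
}

# Apply a log10 free-parameter vector to the problem's params/genes.
apply_theta <- function(problem, theta) {
  params <- problem$params; genes <- problem$genes
  for (i in seq_len(nrow(problem$free))) {
    row <- problem$free[i, ]
    val <- 10^theta[i]
    if (row$scope == "nfkb") params[[row$name]] <- val
    else genes[[row$gene]][[row$name]] <- val
  }
  list(params = params, genes = genes)
}

# Model series for every dataset under one simulation of the full system.
predict_datasets <- function(problem, theta, forcing) {
  mdl <- apply_theta(problem, theta)
  all_times <- sort(unique(c(0, unlist(lapply(problem$datasets, `[[`, "times")))))
  traj <- simulate_nfkb(mdl$params, forcing, genes = mdl$genes,
                        t_grid = all_times, area_ratio = problem$area_ratio)
  rest <- if (length(mdl$genes)) resting_state(mdl$params, mdl$genes) else NULL
  lapply(problem$datasets, function(ds) {
    idx <- match(ds$times, all_times)
    if (ds$kind == "nci") {
      as.numeric(traj$nci[idx])
    } else {
      col <- paste0("gene_", ds$gene, "_R")
      R0 <- rest[col]
      if (R0 <= 1e-6) return(rep(NA_real_, length(idx)))
      as.numeric(traj$states[idx, col] / R0)
    }
  })
}

total_distance <- function(problem, theta, forcing) {
  pred <- tryCatch(predict_datasets(problem, theta, forcing),
                   error = function(e) NULL)
  if (is.null(pred)) return(Inf)
  d <- 0
  for (i in seq_along(pred)) {
    if (any(!is.finite(pred[[i]]))) return(Inf)
    d <- d + fit_distance(problem$datasets[[i]]$values, pred[[i]])
  }
  d
}

#' Fit model parameters to observed time courses
#'
#' Two-stage optimization of the summed [fit_distance()] over the free
#' parameters, on a log10 scale within the box given by each parameter's
#' uncertainty degree: (1) a single-chain Metropolis random walk for global
#' exploration; (2) Levenberg-Marquardt refinement (on squared relative
#' residuals) started from the best explored state, with box constraints
#' enforced by projection. The refined result is kept only if it improves
#' the distance, so the final distance never exceeds the exploration
#' optimum.
#'
#' @param problem a [fit_problem()].
#' @param forcing the [forcing_signal()] under which the data were taken.
#' @param mcmc list of exploration settings: \code{n_steps} (default 1500),
#'   \code{step_scale} (proposal sd = step_scale * degree per parameter,
#'   default 0.12), \code{temperature} (default 0.02).
#' @param lm list of refinement settings: \code{max_iter} (default 50).
#' @param seed integer seed (required).
#' @return an object of class \code{fit_result}: \code{params},
#'   \code{genes} (fitted), \code{theta} (log10 free values),
#'   \code{distance}, \code{distance_per_dataset}, \code{accepted}
#'   (MCMC acceptance count), \code{lm_improved}, \code{lm_warning}
#'   (message when the refinement stopped early; the best explored state
#'   is returned regardless), \code{seed}, \code{trace} (accepted-state
#'   distances).
#' @export
fit_model <- function(problem, forcing, mcmc = list(), lm = list(), seed) {
  if (missing(seed)) stop("fit_model requires an explicit seed")
  stopifnot(inherits(problem, "fit_problem"))
  n_steps <- mcmc$n_steps %||% 1500
  step_scale <- mcmc$step_scale %||% 0.12
  temperature <- mcmc$temperature %||% 0.02
  max_iter <- lm$max_iter %||% 50
  set.seed(seed)

  theta0 <- log10(problem$free$init)
  lo <- theta0 - problem$free$degree
  hi <- theta0 + problem$free$degree
  clamp <- function(th) pmin(pmax(th, lo), hi)

  # stage 1: Metropolis exploration
  th <- theta0
  d_cur <- total_distance(problem, th, forcing)
  best_th <- th; best_d <- d_cur
  accepted <- 0L
  trace <- numeric(0)
  sdv <- step_scale * pmax(problem$free$degree, 0.05)
  for (s in seq_len(n_steps)) {
    prop <- clamp(th + stats::rnorm(length(th), 0, sdv))
    d_prop <- total_distance(problem, prop, forcing)
    if (is.finite(d_prop) &&
        (d_prop <= d_cur ||
         stats::runif(1) < exp(-(d_prop - d_cur) / temperature))) {
      th <- prop; d_cur <- d_prop; accepted <- accepted + 1L
      trace <- c(trace, d_cur)
      if (d_cur < best_d) { best_d <- d_cur; best_th <- th }
    }
  }

  # stage 2: LM on log10 parameters, squared relative residuals
  resid_fn <- function(th) {
    th <- clamp(th)
    pred <- tryCatch(predict_datasets(problem, th, forcing),
                     error = function(e) NULL)
    if (is.null(pred)) return(rep(1e3, sum(vapply(problem$datasets, function(d)
      length(d$values), numeric(1)))))
    unlist(lapply(seq_along(pred), function(i) {
      X <- problem$datasets[[i]]$values; x <- pred[[i]]
      x[!is.finite(x)] <- 1e6
      den <- pmax(X, x)
      r <- ifelse(den > 0, (X - x) / den, 0)
      r / sqrt(length(r))
    }))
  }
  lm_improved <- FALSE
  lm_warning <- NULL
  lm_fit <- tryCatch(
    withCallingHandlers(
      minpack.lm::nls.lm(par = best_th, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = max_iter)),
      warning = function(w) {
        lm_warning <<- conditionMessage(w)
        invokeRestart("muffleWarning")
      }),
    error = function(e) NULL)
  final_th <- best_th; final_d <- best_d
  if (!is.null(lm_fit)) {
    th_lm <- clamp(lm_fit$par)
    d_lm <- total_distance(problem, th_lm, forcing)
    if (is.finite(d_lm) && d_lm <= best_d) {
      final_th <- th_lm; final_d <- d_lm; lm_improved <- d_lm < best_d
    }
  }

  mdl <- apply_theta(problem, final_th)
  pred <- predict_datasets(problem, final_th, forcing)
  per_ds <- vapply(seq_along(pred), function(i)
    fit_distance(problem$datasets[[i]]$values, pred[[i]]), numeric(1))
  structure(list(params = mdl$params, genes = mdl$genes, theta = final_th,
                 free = problem$free, distance = final_d,
                 distance_per_dataset = per_ds, accepted = accepted,
                 lm_improved = lm_improved, lm_warning = lm_warning,
                 seed = seed, trace = trace),
            class = "fit_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> distance = %.4g over %d dataset(s), %d accepted moves%s\n",
              x$distance, length(x$distance_per_dataset), x$accepted,
              if (x$lm_improved) " (LM refined)" else ""))
  invisible(x)
}

#' Fit gene parameters for a panel of expression profiles
#'
#' Independent telegraph-model fits per gene, keeping the shared dynamics
#' parameters fixed (from a prior NCI fit) and varying only that gene's
#' parameters. Used to compare fitted mRNA degradation rates between
#' oscillating and accumulating expression patterns.
#'
#' @param fold_changes matrix of observed fold changes, genes in rows
#'   (rownames = gene ids), timepoints in columns.
#' @param times timepoints (min) for the columns.
#' @param params the fixed shared [kinetic_params()].
#' @param forcing the [forcing_signal()].
#' @param gene_init initial [gene_params()] for every gene; the default
#'   centres the mRNA-turnover search geometrically between fast
#'   (oscillating) and slow (accumulating) regimes.
#' @param free which gene parameters to fit
#'   (default all five).
#' @param gene_degree log10 half-width of the per-parameter search box
#'   (see [fit_problem()]).
#' @param mcmc,lm settings passed to [fit_model()] (panel default
#'   \code{n_steps = 600}).
#' @param seed integer seed; gene g uses \code{seed + index}.
#' @return list with \code{table} (data frame: gene, distance, fitted
#'   d_R_G, k_on_G, convergence flag) and \code{fits} (per-gene
#'   \code{fit_result} or error message).
#' @export
fit_gene_panel <- function(fold_changes, times, params, forcing,
                           gene_init = gene_params(d_R_G = 0.4),
                           free = c("k_on_G", "k_on0_G", "k_off_G",
                                    "k_off0_G", "d_R_G"),
                           gene_degree = 1.5,
                           mcmc = list(n_steps = 600), lm = list(), seed) {
  if (missing(seed)) stop("fit_gene_panel requires an explicit seed")
  ids <- rownames(fold_changes)
  if (is.null(ids)) stop("fold_changes needs gene ids as rownames")
  fits <- vector("list", length(ids)); names(fits) <- ids
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    gid <- ids[i]
    res <- try({
      pb <- fit_problem(
        datasets = list(list(kind = "fold_change", gene = "g",
                             times = times,
                             values = as.numeric(fold_changes[gid, ]))),
        params = params, genes = list(g = gene_init),
        free_genes = list(g = free), gene_degree = gene_degree)
      fit_model(pb, forcing, mcmc = mcmc, lm = lm, seed = seed + i)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      fits[[gid]] <- attr(res, "condition")$message
      rows[[i]] <- data.frame(gene = gid, distance = NA_real_,
                              d_R_G = NA_real_, k_on_G = NA_real_,
                              ok = FALSE)
    } else {
      fits[[gid]] <- res
      rows[[i]] <- data.frame(gene = gid, distance = res$distance,
                              d_R_G = res$genes$g$d_R_G,
                              k_on_G = res$genes$g$k_on_G, ok = TRUE)
    }
  }
  list(table = do.call(rbind, rows), fits = fits)
}
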