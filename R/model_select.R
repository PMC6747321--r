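#' Default parameter grids for the cross-validated grid search
#'
#' The grids swept by [cv_select_model()]: the IDW power exponents, the
#' variogram sill / range / nugget values, the candidate variogram shapes
#' and the co-kriging beta weights.  Ranges are expressed in the units of
#' the distance metric (degrees by default).
#'
#' @return named list of numeric/character vectors.
#' @export
default_grids <- function() {
  list(
    idp    = c(0.1, 0.3, 0.5, 0.8, 2, 5),
    sill   = c(1, 10, 100, 250, 500, 600, 700, 800, 900),
    range  = c(0.1, 0.5, 1, 10, 20, 50, 80),
    nugget = c(0.00001, 0.0001, 0.001, 0.01, 0.1, 1, 10, 100, 200, 50),
    beta   = c(0.05, 0.12, 0.2, 0.5, 0.9, 1.5, 3, 1),
    model  = c("gaussian", "circular", "exponential")
  )
}

# deterministic fold assignment: uniform random permutation under the given
# seed, folds as equal in size as possible
assign_folds <- function(n, k, seed) {
  if (k < 2) stop("cross-validation needs k >= 2 folds")
  if (k > n) stop("more folds (", k, ") than stations (", n, ")")
  with_seed(seed, rep_len(seq_len(k), n)[sample.int(n)])
}

#' Grid-searched, k-fold cross-validated interpolator selection
#'
#' Partitions the stations of one hourly dataset into `k` folds (random
#' permutation under `seed`), and for every candidate technique and
#' parameter combination computes the root-mean-squared error of held-out
#' predictions pooled over all folds.  The specification with the smallest
#' RMSE wins; exact ties are broken by a fixed deterministic order —
#' technique order IDW < simple kriging < ordinary kriging < co-kriging,
#' then lexicographic parameter order (variogram model in grid order, then
#' range, sill, nugget, beta).
#'
#' The beta grid is swept for co-kriging only; simple kriging uses the
#' per-fold sample mean of the training readings as its known mean.
#' Co-kriging candidates are only evaluated when `secondary` is supplied.
#' Parameter combinations whose kriging system is numerically singular are
#' dropped from the competition.
#'
#' @param readings one hour's station readings: data frame with `lon`,
#'   `lat`, `value` (and optionally `station_id`).
#' @param secondary collocated secondary-pollutant readings, or `NULL`.
#' @param grids parameter grids as from [default_grids()]; any element may
#'   be overridden.
#' @param k number of folds (default 5).
#' @param seed RNG seed controlling the fold split.
#' @param metric see [dist_matrix()].
#' @param techniques subset of techniques to consider.
#' @return object of class `cv_selection`: list with `best` (an
#'   [interp_spec()]), `best_rmse`, `rmse` (the full RMSE table) and
#'   `folds` (the fold assignment).
#' @export
cv_select_model <- function(readings, secondary = NULL, grids = list(),
                            k = 5, seed = 20170324, metric = "euclidean",
                            techniques = c("IDW", "simple_kriging",
                                           "ordinary_kriging", "cokriging")) {
  readings <- dedupe_stations(readings)
  n <- nrow(readings)
  grids <- modifyList(default_grids(), grids)
  techniques <- match.arg(techniques, several.ok = TRUE)
  if (is.null(secondary)) techniques <- setdiff(techniques, "cokriging")
  fold <- assign_folds(n, k, seed)
  t_all <- if ("cokriging" %in% techniques) match_secondary(readings, secondary)
  if ("cokriging" %in% techniques && is.null(t_all)) {
    warning("secondary readings do not cover the stations; dropping cokriging")
    techniques <- setdiff(techniques, "cokriging")
  }

  # per-fold geometry, computed once
  folds <- lapply(seq_len(k), function(f) {
    tr <- which(fold != f); te <- which(fold == f)
    list(tr = tr, te = te,
         D  = dist_matrix(readings$lon[tr], readings$lat[tr],
                          readings$lon[tr], readings$lat[tr], metric = metric),
         d0 = dist_matrix(readings$lon[tr], readings$lat[tr],
                          readings$lon[te], readings$lat[te], metric = metric))
  })
  obs <- readings$value
  rmse_of <- function(pred_by_fold) {
    err2 <- 0
    for (f in seq_len(k)) err2 <- err2 + sum((pred_by_fold[[f]] - obs[folds[[f]]$te])^2)
    sqrt(err2 / n)
  }

  rows <- list()
  add_row <- function(technique, params, rmse) {
    rows[[length(rows) + 1]] <<- c(list(technique = technique), params,
                                   list(rmse = rmse))
  }

  if ("IDW" %in% techniques) {
    for (idp in grids$idp) {
      preds <- lapply(folds, function(fd) {
        w <- fd$d0^(-idp)
        vapply(seq_along(fd$te), function(j) {
          hit <- which(fd$d0[, j] < COINCIDENCE_TOL)
          if (length(hit)) obs[fd$tr][hit[1]]
          else sum(w[, j] * obs[fd$tr]) / sum(w[, j])
        }, numeric(1))
      })
      add_row("IDW", list(idp = idp, model = NA, sill = NA, range = NA,
                          nugget = NA, beta = NA), rmse_of(preds))
    }
  }

  krig_techs <- intersect(c("simple_kriging", "ordinary_kriging", "cokriging"),
                          techniques)
  if (length(krig_techs)) {
    for (model in grids$model) for (rg in grids$range) {
      # shape matrices shared across the sill x nugget sub-grid
      shp <- lapply(folds, function(fd)
        list(G = semivar_shape(model, fd$D, rg),
             g0 = semivar_shape(model, fd$d0, rg),
             z0 = fd$D == 0, z00 = fd$d0 == 0))
      for (sill in grids$sill) for (nug in grids$nugget) {
        ok_sol <- vector("list", k)   # reused by cokriging
        pred_sk <- pred_ok <- sec_term <- vector("list", k)
        bad <- FALSE
        for (f in seq_len(k)) {
          fd <- folds[[f]]; sh <- shp[[f]]
          G <- nug + sill * sh$G;  G[sh$z0] <- 0
          g0 <- nug + sill * sh$g0; g0[sh$z00] <- 0
          if ("simple_kriging" %in% krig_techs) {
            res <- try({
              sol <- krige_solve((nug + sill) - G, (nug + sill) - g0, "simple")
              m <- mean(obs[fd$tr])
              pred_sk[[f]] <- m + drop(crossprod(sol$lambda, obs[fd$tr] - m))
            }, silent = TRUE)
            if (inherits(res, "try-error")) { bad <- TRUE; break }
          }
          if (any(c("ordinary_kriging", "cokriging") %in% krig_techs)) {
            res <- try({
              sol <- krige_solve(G, g0, "ordinary")
              ok_sol[[f]] <- sol
              pred_ok[[f]] <- drop(crossprod(sol$lambda, obs[fd$tr]))
              if ("cokriging" %in% krig_techs) {
                t_tr <- t_all[fd$tr]
                sec_term[[f]] <- drop(crossprod(sol$lambda, t_tr - mean(t_tr)))
              }
            }, silent = TRUE)
            if (inherits(res, "try-error")) { bad <- TRUE; break }
          }
        }
        base <- list(idp = NA, model = model, sill = sill, range = rg,
                     nugget = nug, beta = NA)
        if ("simple_kriging" %in% krig_techs)
          add_row("simple_kriging", base, if (bad) NA else rmse_of(pred_sk))
        if ("ordinary_kriging" %in% krig_techs)
          add_row("ordinary_kriging", base, if (bad) NA else rmse_of(pred_ok))
        if ("cokriging" %in% krig_techs) for (bt in grids$beta) {
          base$beta <- bt
          add_row("cokriging", base,
                  if (bad) NA
                  else rmse_of(Map(function(p, s) p + bt * s, pred_ok, sec_term)))
        }
      }
    }
  }

  tab <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  # rows were appended in tie-break order within each technique; order the
  # techniques themselves, keeping insertion order inside a technique
  tech_rank <- match(tab$technique,
                     c("IDW", "simple_kriging", "ordinary_kriging", "cokriging"))
  tab <- tab[order(tech_rank), , drop = FALSE]
  rownames(tab) <- NULL
  cand <- which(!is.na(tab$rmse))
  if (!length(cand)) stop("every candidate interpolator failed; cannot select a model")
  best_i <- cand[which.min(tab$rmse[cand])]
  b <- tab[best_i, ]
  best <- switch(as.character(b$technique),
    IDW = interp_spec("IDW", idp = b$idp),
    simple_kriging = interp_spec("simple_kriging",
      variogram = variogram_spec(b$model, b$nugget, b$sill, b$range)),
    ordinary_kriging = interp_spec("ordinary_kriging",
      variogram = variogram_spec(b$model, b$nugget, b$sill, b$range)),
    cokriging = interp_spec("cokriging",
      variogram = variogram_spec(b$model, b$nugget, b$sill, b$range),
      beta = b$beta,
      secondary_pollutant = attr(secondary, "pollutant")))
  structure(list(best = best, best_rmse = b$rmse, rmse = tab, folds = fold,
                 seed = seed, k = k),
            class = "cv_selection")
}

#' @export
print.cv_selection <- function(x, ...) {
  cat(sprintf("<cv_selection: %d-fold, %d candidates, best RMSE %.4g>\n",
              x$k, nrow(x$rmse), x$best_rmse))
  print(x$best)
  invisible(x)
}
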