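#' StDev*Coefficient contour field for one field kind
#'
#' For every retained descriptor column of the requested field, the
#' contour value at its grid point is sd(X_j) * b_j (training-column
#' standard deviation times PLS regression coefficient); masked grid
#' points carry exactly 0.
#'
#' @param model a `pae_pls` fitted on the assembled descriptors
#' @param desc the `pae_descriptors` the model was fit on
#' @param grid the `pae_grid` the blocks were evaluated on
#' @param kind field kind, e.g. `"CoMFA_S"` or `"CoMSIA_H"`
#' @return a `pae_contour_field`: `values` over the full grid, plus the
#'   grid and kind
#' @export
stdev_coeff_field <- function(model, desc, grid, kind) {
  rows <- desc$map$field == kind
  if (!any(rows)) {
    stop("field kind ", kind, " not present in the descriptor map",
         call. = FALSE)
  }
  vals <- numeric(prod(grid$dims))
  cols <- desc$map$column[rows]
  vals[desc$map$point[rows]] <- model$x_sd[cols] * model$coef[cols]
  structure(list(kind = kind, grid = grid, values = vals),
            class = "pae_contour_field")
}

#' @export
print.pae_contour_field <- function(x, ...) {
  nz <- sum(x$values != 0)
  cat(sprintf("<pae_contour_field %s> %d grid points, %d nonzero\n",
              x$kind, length(x$values), nz))
  invisible(x)
}

# 6-neighborhood connected components on the grid, over a logical mask
# of selected points (canonical x-fastest linear indexing).
grid_components <- function(mask, dims) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  labels <- integer(length(mask))
  comp <- 0L
  for (start in which(mask)) {
    if (labels[start] != 0L) next
    comp <- comp + 1L
    queue <- start
    labels[start] <- comp
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      i0 <- v - 1L
      ix <- i0 %% nx
      iy <- (i0 %/% nx) %% ny
      iz <- i0 %/% (nx * ny)
      nb <- integer(0)
      if (ix > 0L)      nb <- c(nb, v - 1L)
      if (ix < nx - 1L) nb <- c(nb, v + 1L)
      if (iy > 0L)      nb <- c(nb, v - nx)
      if (iy < ny - 1L) nb <- c(nb, v + nx)
      if (iz > 0L)      nb <- c(nb, v - nx * ny)
      if (iz < nz - 1L) nb <- c(nb, v + nx * ny)
      nb <- nb[mask[nb] & labels[nb] == 0L]
      labels[nb] <- comp
      queue <- c(queue, nb)
    }
  }
  labels
}

#' Extract favorable / unfavorable contour regions
#'
#' Thresholds are percentiles of the signed nonzero field values:
#' points strictly above the `fav_percentile` quantile are favorable
#' (the green/blue analog), points strictly below the
#' `unfav_percentile` quantile unfavorable (yellow/red). Each label set
#' is grouped into connected components under the 6-neighborhood.
#'
#' @param cf a `pae_contour_field`
#' @param fav_percentile,unfav_percentile percentile levels (default
#'   80 / 20)
#' @return a `pae_contour_regions` list: `regions` (data.frame with id,
#'   sign, n_points, centroid, level) and `labels` (per grid point:
#'   0 = unlabeled, else region id)
#' @export
extract_regions <- function(cf, fav_percentile = 80, unfav_percentile = 20) {
  nz <- cf$values[cf$values != 0]
  labels <- integer(length(cf$values))
  empty <- structure(list(regions = data.frame(), labels = labels,
                          levels = c(fav = NA_real_, unfav = NA_real_)),
                     class = "pae_contour_regions")
  if (!length(nz) || diff(range(nz)) == 0) {
    warning("constant contour field: no regions extracted")
    return(empty)
  }
  lev_fav <- unname(quantile(nz, fav_percentile / 100))
  lev_unfav <- unname(quantile(nz, unfav_percentile / 100))
  pts <- grid_points(cf$grid)
  out <- list()
  next_id <- 0L
  for (side in c("favorable", "unfavorable")) {
    mask <- if (side == "favorable") {
      cf$values != 0 & cf$values > lev_fav
    } else {
      cf$values != 0 & cf$values < lev_unfav
    }
    comp <- grid_components(mask, cf$grid$dims)
    for (id in seq_len(max(comp, 0L))) {
      sel <- comp == id
      next_id <- next_id + 1L
      labels[sel] <- next_id
      out[[next_id]] <- data.frame(
        id = next_id, sign = side, n_points = sum(sel),
        cx = mean(pts[sel, 1]), cy = mean(pts[sel, 2]),
        cz = mean(pts[sel, 3]),
        level = if (side == "favorable") lev_fav else lev_unfav)
    }
  }
  structure(list(regions = if (length(out)) do.call(rbind, out)
                           else data.frame(),
                 labels = labels,
                 levels = c(fav = lev_fav, unfav = lev_unfav)),
            class = "pae_contour_regions")
}

#' Export contour regions as a JSON summary
#'
#' @param reg a `pae_contour_regions`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_regions_json <- function(reg, path) {
  jsonlite::write_json(list(levels = as.list(reg$levels),
                            regions = reg$regions),
                       path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
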