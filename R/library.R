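#' The composition sweep of the tissue library
#'
#' The constrained Cartesian product of vascularity 0.5-5% (step 0.5), tumor
#' cellularity 10-95% (step 5) and stromal cellularity 5-95% (step 5), keeping
#' combinations whose total occupied fraction does not exceed 100%. The order
#' is deterministic (vascularity outermost, then tumor, then stromal) and the
#' sweep contains 1,530 compositions.
#'
#' @return A tibble with columns `vascular`, `tumor`, `stromal` and a
#'   `composition_index` running id.
#' @examples
#' nrow(sweep_compositions())
#' @export
sweep_compositions <- function() {
  grid <- expand.grid(stromal = seq(5, 95, by = 5),
                      tumor = seq(10, 95, by = 5),
                      vascular = seq(0.5, 5, by = 0.5))
  grid <- grid[grid$vascular + grid$tumor + grid$stromal <= 100, ]
  out <- tibble::as_tibble(grid[, c("vascular", "tumor", "stromal")])
  out <- out[order(out$vascular, out$tumor, out$stromal), ]
  out$composition_index <- seq_len(nrow(out))
  out
}

#' Classify a stabilized average pO2 into one of five classes
#'
#' Classes partition 0-60 mmHg in 12 mmHg increments: class 0 is 0-12, class
#' 1 is 12-24, class 2 is 24-36, class 3 is 36-48, class 4 is above 48 (up to
#' 60). Bins are half-open at the top except the last, so a tissue at exactly
#' 36 mmHg belongs to class 3.
#'
#' @param average_po2 Numeric vector of average pO2 values in `[0, 60]` mmHg.
#' @return Integer class indices 0..4.
#' @examples
#' classify_po2(c(29.89, 0, 36, 60))
#' @export
classify_po2 <- function(average_po2) {
  if (any(!is.finite(average_po2)) || any(average_po2 < 0) || any(average_po2 > 60))
    stop("average pO2 must lie in [0, 60] mmHg", call. = FALSE)
  po2_class(average_po2)
}

#' Build a library of stabilized tissues
#'
#' For each composition: sample a layout, relax overlaps, stabilize the
#' oxygen field, and record the stabilized average and its class. Each
#' composition gets its own RNG seed derived from the global seed and the
#' composition index, so any entry can be regenerated independently with
#' [entry_layout()].
#'
#' @param compositions A tibble of compositions (default the full
#'   [sweep_compositions()] sweep; pass a subset for smaller builds).
#' @param params Model parameters.
#' @param seed Global integer seed.
#' @param keep_layouts Keep the relaxed layouts as a list-column (memory-heavy
#'   for large sweeps; they can always be regenerated from the seeds).
#' @param progress Print a line every `progress` entries (0 = quiet).
#' @return A `tissue_library` tibble: composition columns, `seed`,
#'   `avg_po2_mmHg`, `class`, `iterations`, `converged`, `jammed` and
#'   optionally `layout`.
#' @export
build_library <- function(compositions = sweep_compositions(),
                          params = ox_params(), seed = 1L,
                          keep_layouts = FALSE, progress = 0L) {
  stopifnot(is.data.frame(compositions),
            all(c("vascular", "tumor", "stromal") %in% names(compositions)))
  if (!"composition_index" %in% names(compositions))
    compositions$composition_index <- seq_len(nrow(compositions))
  n <- nrow(compositions)
  avg <- iter <- numeric(n)
  conv <- jam <- logical(n)
  seeds <- integer(n)
  layouts <- if (keep_layouts) vector("list", n) else NULL
  for (i in seq_len(n)) {
    comp <- tissue_composition(compositions$vascular[i], compositions$tumor[i],
                               compositions$stromal[i])
    seeds[i] <- as.integer(derive_seed(seed, "library",
                                       compositions$composition_index[i]))
    lay <- relax_layout(sample_layout(comp, params, seeds[i]), params)
    st <- stabilize_oxygen(lay, params)
    avg[i] <- st$report$average_po2
    iter[i] <- st$report$iterations
    conv[i] <- st$report$converged
    jam[i] <- attr(lay, "relaxation")$jammed
    if (keep_layouts) layouts[[i]] <- lay
    if (progress > 0 && i %% progress == 0)
      message(sprintf("library %d/%d: (%.1f,%g,%g) -> %.2f mmHg", i, n,
                      comp$vascular, comp$tumor, comp$stromal, avg[i]))
  }
  out <- tibble::tibble(
    composition_index = compositions$composition_index,
    vascular = compositions$vascular, tumor = compositions$tumor,
    stromal = compositions$stromal, seed = seeds,
    avg_po2_mmHg = avg, class = po2_class(avg),
    iterations = iter, converged = conv, jammed = jam)
  if (keep_layouts) out$layout <- layouts
  tibble::new_tibble(out, global_seed = as.integer(seed),
                     class = "tissue_library")
}

#' Regenerate the relaxed layout of a library entry
#'
#' @param entry A one-row slice of a `tissue_library`.
#' @param params The parameters the library was built with.
#' @return The relaxed `tissue_layout`.
#' @export
entry_layout <- function(entry, params = ox_params()) {
  comp <- tissue_composition(entry$vascular[1], entry$tumor[1], entry$stromal[1])
  relax_layout(sample_layout(comp, params, entry$seed[1]), params)
}

#' Library entry closest to a target pO2
#'
#' @param library A `tissue_library`.
#' @param target_po2 Target average pO2 (mmHg).
#' @return The single entry minimizing `|avg_po2_mmHg - target_po2|`; ties go
#'   to the lower composition index.
#' @export
find_closest <- function(library, target_po2) {
  stopifnot(nrow(library) > 0)
  d <- abs(library$avg_po2_mmHg - target_po2)
  library[which.min(d), ] # which.min takes the first (lowest index) on ties
}

#' All library entries within a tolerance of a target pO2
#'
#' The representative set of a measured voxel: entries whose stabilized
#' average lies within `tol` mmHg of the target.
#'
#' @inheritParams find_closest
#' @param tol Half-width of the acceptance band (mmHg).
#' @return The matching sub-library (possibly empty).
#' @export
select_representatives <- function(library, target_po2, tol = 3.5) {
  library[abs(library$avg_po2_mmHg - target_po2) <= tol, ]
}

#' Replicate statistics of a composition
#'
#' Generates `n` independent tissues of the same composition (distinct seeds),
#' stabilizes each, and returns the mean and sample standard deviation of the
#' stabilized averages.
#'
#' @param comp A composition.
#' @param n Number of replicates.
#' @param params Model parameters.
#' @param seed Global seed; replicate i uses a seed derived from `(seed, i)`.
#' @return A list with `mean`, `sd`, and the per-replicate tibble `replicates`.
#' @export
replicate_statistics <- function(comp, n = 25, params = ox_params(), seed = 1L) {
  stopifnot(n >= 2)
  comp <- as_composition(comp)
  avg <- numeric(n); conv <- logical(n); seeds <- integer(n)
  for (i in seq_len(n)) {
    seeds[i] <- as.integer(derive_seed(seed, "replicates", i))
    lay <- relax_layout(sample_layout(comp, params, seeds[i]), params)
    st <- stabilize_oxygen(lay, params)
    avg[i] <- st$report$average_po2
    conv[i] <- st$report$converged
  }
  list(mean = mean(avg), sd = stats::sd(avg),
       replicates = tibble::tibble(replicate = seq_len(n), seed = seeds,
                                   avg_po2_mmHg = avg, converged = conv))
}

# Binning shared by classify_po2 and build_library; the top class is open
# above 48 mmHg so library entries slightly above the nominal 60 mmHg vascular
# level (possible at high vascularity and sparse cellularity) stay class 4.
po2_class <- function(average_po2) {
  as.integer(pmin(floor(average_po2 / 12), 4))
}
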