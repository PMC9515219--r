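#' Parcellation metadata
#'
#' Region identities and side information for a cortical parcellation:
#' hemisphere membership, a unit-sphere centroid per region, and categorical
#' community (typically 7 intrinsic functional networks) and hierarchy
#' (typically 4 laminar-differentiation levels) labels. Every parcellated
#' container in the package is aligned to one of these.
#'
#' @param region_id character vector of unique region identifiers, ordered.
#'   The package convention is `hemisphere_regionname` in lower case, e.g.
#'   `lh_insula`.
#' @param hemisphere character vector, one of `"L"`/`"R"` per region.
#' @param centroid numeric matrix, regions x 3, each row a unit vector giving
#'   the region centroid on a common sphere.
#' @param community character or factor of community labels per region.
#' @param hierarchy character or factor of hierarchy labels per region.
#' @return An object of class `parcellation_meta`.
#' @export
parcellation_meta <- function(region_id, hemisphere, centroid, community, hierarchy) {
  region_id <- as.character(region_id)
  n <- length(region_id)
  if (n < 1L) stopf("a parcellation needs at least one region")
  if (anyDuplicated(region_id))
    stopf("duplicate region_id: %s",
          paste(unique(region_id[duplicated(region_id)]), collapse = ", "))
  hemisphere <- as.character(hemisphere)
  if (length(hemisphere) != n || !all(hemisphere %in% c("L", "R")))
    stopf("hemisphere must be 'L' or 'R' for every region")
  centroid <- as.matrix(centroid)
  if (!is.numeric(centroid) || nrow(centroid) != n || ncol(centroid) != 3L)
    stopf("centroid must be a numeric regions x 3 matrix")
  norms <- sqrt(rowSums(centroid^2))
  if (any(abs(norms - 1) > 1e-9))
    stopf("centroids must lie on the unit sphere (|norm - 1| <= 1e-9)")
  community <- factor(as.character(community))
  hierarchy <- factor(as.character(hierarchy))
  if (length(community) != n || length(hierarchy) != n)
    stopf("community and hierarchy labels must cover every region")
  if (nlevels(community) < 1L || nlevels(hierarchy) < 1L)
    stopf("label sets must be non-empty")
  rownames(centroid) <- region_id
  structure(list(region_id = region_id, hemisphere = hemisphere,
                 centroid = centroid, community = community,
                 hierarchy = hierarchy),
            class = "parcellation_meta")
}

#' @export
print.parcellation_meta <- function(x, ...) {
  cat(sprintf("parcellation_meta: %d regions (%d L / %d R), %d communities, %d hierarchy levels\n",
              length(x$region_id), sum(x$hemisphere == "L"), sum(x$hemisphere == "R"),
              nlevels(x$community), nlevels(x$hierarchy)))
  invisible(x)
}

n_regions <- function(meta) length(meta$region_id)

#' Restrict a parcellation to a subset of regions
#'
#' @param meta a [parcellation_meta()].
#' @param idx integer or logical index, or character region ids.
#' @return A `parcellation_meta` over the selected regions, order preserved.
#' @export
subset_meta <- function(meta, idx) {
  if (is.character(idx)) idx <- match(idx, meta$region_id)
  if (anyNA(idx)) stopf("unknown region in subset")
  parcellation_meta(meta$region_id[idx], meta$hemisphere[idx],
                    meta$centroid[idx, , drop = FALSE],
                    as.character(meta$community)[idx],
                    as.character(meta$hierarchy)[idx])
}

#' Scalar map over a parcellation
#'
#' One real value per region. Missing regions are carried as an explicit
#' mask (non-finite values are masked, never silently imputed).
#'
#' @param values numeric vector, one value per region of `meta`.
#' @param meta the [parcellation_meta()] the values are aligned to.
#' @param name label for the map.
#' @return An object of class `parcel_map` with fields `values` (named by
#'   region), `mask` (TRUE where missing), `name`, `meta`.
#' @export
parcel_map <- function(values, meta, name = "map") {
  values <- as.numeric(values)
  if (length(values) != n_regions(meta))
    stopf("map '%s' has %d values for %d regions", name, length(values), n_regions(meta))
  mask <- !is.finite(values)
  values[mask] <- NA_real_
  names(values) <- meta$region_id
  structure(list(values = values, mask = mask, name = name, meta = meta),
            class = "parcel_map")
}

#' @export
print.parcel_map <- function(x, ...) {
  cat(sprintf("parcel_map '%s': %d regions (%d masked), range [%.4g, %.4g]\n",
              x$name, length(x$values), sum(x$mask),
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Effect-size matrix (regions x conditions)
#'
#' The substrate of the shared-dimension analysis: per-condition effect-size
#' maps stacked column-wise.
#'
#' @param values numeric matrix, regions x conditions.
#' @param meta aligned [parcellation_meta()].
#' @param conditions ordered condition names (defaults to column names).
#' @export
effect_matrix <- function(values, meta, conditions = colnames(values)) {
  values <- as.matrix(values)
  if (nrow(values) != n_regions(meta))
    stopf("effect matrix has %d rows for %d regions", nrow(values), n_regions(meta))
  if (is.null(conditions)) conditions <- paste0("cond", seq_len(ncol(values)))
  if (length(conditions) != ncol(values)) stopf("condition names do not match columns")
  dimnames(values) <- list(meta$region_id, conditions)
  structure(list(values = values, conditions = conditions, meta = meta),
            class = "effect_matrix")
}

#' Depth-wise intracortical intensity profiles
#'
#' @param intensities numeric matrix, regions x depths, sampled from the pial
#'   surface (first column) to the white-matter boundary (last column).
#' @param meta aligned [parcellation_meta()].
#' @param depth_fractions strictly increasing depth fractions in \[0, 1\]
#'   (0 = pial, 1 = white); defaults to an even grid over \[0, 1\].
#' @param source free-text provenance tag (e.g. "14-depth in vivo").
#' @export
profile_set <- function(intensities, meta, depth_fractions = NULL, source = "profiles") {
  intensities <- as.matrix(intensities)
  if (nrow(intensities) != n_regions(meta))
    stopf("profile set has %d rows for %d regions", nrow(intensities), n_regions(meta))
  nd <- ncol(intensities)
  if (is.null(depth_fractions)) depth_fractions <- seq(0, 1, length.out = nd)
  if (length(depth_fractions) != nd || any(diff(depth_fractions) <= 0) ||
      min(depth_fractions) < 0 || max(depth_fractions) > 1)
    stopf("depth_fractions must be strictly increasing within [0, 1]")
  rownames(intensities) <- meta$region_id
  structure(list(intensities = intensities, depth_fractions = depth_fractions,
                 source = source, meta = meta),
            class = "profile_set")
}

#' Symmetric region-by-region connectivity / similarity matrix
#'
#' Symmetrized on construction; asymmetries beyond 1e-9 are rejected.
#'
#' @param values numeric square matrix aligned to `meta`.
#' @param meta aligned [parcellation_meta()].
#' @param kind one of `"microstructural"`, `"functional"`, `"affinity"`.
#' @export
connectivity_matrix <- function(values, meta,
                                kind = c("microstructural", "functional", "affinity")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  n <- n_regions(meta)
  if (nrow(values) != n || ncol(values) != n)
    stopf("connectivity matrix must be %d x %d", n, n)
  if (!all(is.finite(values))) stopf("connectivity matrix contains non-finite entries")
  if (max(abs(values - t(values))) > 1e-9)
    stopf("connectivity matrix is not symmetric (tolerance 1e-9)")
  values <- (values + t(values)) / 2
  dimnames(values) <- list(meta$region_id, meta$region_id)
  structure(list(values = values, kind = kind, meta = meta),
            class = "connectivity_matrix")
}

#' Panel of named multiscale features (regions x features)
#'
#' Houses gradients, profile moments, externopyramidization and transmitter
#' maps side by side for correlation testing and prediction.
#'
#' @param values numeric matrix, regions x features.
#' @param meta aligned [parcellation_meta()].
#' @param features unique feature names (defaults to column names).
#' @param provenance optional per-feature provenance tag
#'   (moment / externopyramidization / gradient / transmitter / other).
#' @export
feature_panel <- function(values, meta, features = colnames(values), provenance = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != n_regions(meta))
    stopf("feature panel has %d rows for %d regions", nrow(values), n_regions(meta))
  if (is.null(features)) features <- paste0("f", seq_len(ncol(values)))
  if (length(features) != ncol(values) || anyDuplicated(features))
    stopf("feature names must be unique and match the column count")
  if (is.null(provenance)) provenance <- rep("other", ncol(values))
  dimnames(values) <- list(meta$region_id, features)
  structure(list(values = values, features = features,
                 provenance = provenance, meta = meta),
            class = "feature_panel")
}

sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Read a parcellated table
#'
#' Reads a delimited text table (tab or comma, sniffed from the header line)
#' whose first column is `region_id`, aligns the rows to `meta`'s region
#' order, and wraps the numeric columns in the narrowest fitting container:
#' a [parcel_map()] for one value column, otherwise an [effect_matrix()]
#' (request `container = "panel"` for a [feature_panel()]).
#'
#' Empty cells become masked (missing) values; any other non-numeric cell is
#' a parse error naming the offending row and column. Files missing regions
#' of `meta`, or containing unknown or duplicated regions, are rejected.
#'
#' @param path file to read.
#' @param meta the [parcellation_meta()] defining region order.
#' @param container `"auto"` (default), `"map"`, `"effects"` or `"panel"`.
#' @return A `parcel_map`, `effect_matrix` or `feature_panel`.
#' @export
read_parcel_table <- function(path, meta, container = c("auto", "map", "effects", "panel")) {
  container <- match.arg(container)
  sep <- sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, colClasses = "character",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stopf("'%s' needs a region_id column plus at least one value column", path)
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stopf("duplicate region in '%s': %s", path,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  unknown <- setdiff(ids, meta$region_id)
  if (length(unknown))
    stopf("unknown region in '%s': %s", path, paste(unknown, collapse = ", "))
  absent <- setdiff(meta$region_id, ids)
  if (length(absent))
    stopf("missing region in '%s': %s", path, paste(absent, collapse = ", "))
  ord <- match(meta$region_id, ids)
  vals <- matrix(NA_real_, nrow = length(ids), ncol = ncol(df) - 1L)
  for (j in seq_len(ncol(df) - 1L)) {
    raw <- df[[j + 1L]][ord]
    empty <- !nzchar(trimws(raw))
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !empty)
    if (length(bad))
      stopf("non-numeric value '%s' in '%s' (region %s, column %s)",
            raw[bad[1L]], path, meta$region_id[bad[1L]], names(df)[j + 1L])
    vals[, j] <- num
  }
  colnames(vals) <- names(df)[-1L]
  if (container == "auto") container <- if (ncol(vals) == 1L) "map" else "effects"
  switch(container,
    map = {
      if (ncol(vals) != 1L) stopf("'%s' has %d value columns; a map needs one", path, ncol(vals))
      parcel_map(vals[, 1L], meta, name = colnames(vals)[1L])
    },
    effects = effect_matrix(vals, meta),
    panel = feature_panel(vals, meta))
}

#' Write a parcellated table
#'
#' Writes a [parcel_map()], [effect_matrix()] or [feature_panel()] as a
#' tab-separated table with `region_id` first, in meta region order, with
#' fixed 15-significant-digit formatting so that write-then-read round-trips
#' values to 1e-12 and repeated writes are byte-identical. Masked values are
#' written as empty cells.
#'
#' @param obj the object to write.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_parcel_table <- function(obj, path) {
  vals <- parcel_values(obj)
  fmt <- function(x) ifelse(is.na(x), "", formatC(x, digits = 15, format = "g"))
  body <- apply(vals, 2L, fmt)
  if (is.null(dim(body))) body <- matrix(body, ncol = ncol(vals))
  lines <- c(paste(c("region_id", colnames(vals)), collapse = "\t"),
             paste(obj$meta$region_id,
                   apply(body, 1L, paste, collapse = "\t"), sep = "\t"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

parcel_values <- function(obj) {
  if (inherits(obj, "parcel_map")) {
    m <- matrix(obj$values, ncol = 1L, dimnames = list(obj$meta$region_id, obj$name))
    m
  } else if (inherits(obj, c("effect_matrix", "feature_panel"))) {
    obj$values
  } else if (inherits(obj, "connectivity_matrix")) {
    obj$values
  } else stopf("unsupported object of class '%s'", class(obj)[1L])
}

restrict_obj <- function(obj, ids) {
  idx <- match(ids, obj$meta$region_id)
  meta <- subset_meta(obj$meta, idx)
  if (inherits(obj, "parcel_map")) parcel_map(obj$values[idx], meta, obj$name)
  else if (inherits(obj, "effect_matrix"))
    effect_matrix(obj$values[idx, , drop = FALSE], meta, obj$conditions)
  else if (inherits(obj, "feature_panel"))
    feature_panel(obj$values[idx, , drop = FALSE], meta, obj$features, obj$provenance)
  else if (inherits(obj, "profile_set"))
    profile_set(obj$intensities[idx, , drop = FALSE], meta, obj$depth_fractions, obj$source)
  else if (inherits(obj, "connectivity_matrix"))
    connectivity_matrix(obj$values[idx, idx, drop = FALSE], meta, obj$kind)
  else stopf("cannot restrict object of class '%s'", class(obj)[1L])
}

#' Align parcellated sources to their common region subset
#'
#' Different data sources cover different region subsets (for instance a
#' histological atlas may lack a few regions per hemisphere that an in vivo
#' atlas provides). `align_sources` restricts every input to the intersection
#' of available regions, preserving the region order of the first input.
#' Idempotent: aligning already-aligned inputs returns them unchanged.
#'
#' @param ... parcellated objects (`parcel_map`, `effect_matrix`,
#'   `feature_panel`, `profile_set`, `connectivity_matrix`), or a single list
#'   of them.
#' @return A list of restricted objects, with attribute `n_common` giving the
#'   intersection size. Errors if the intersection is empty.
#' @export
align_sources <- function(...) {
  objs <- list(...)
  if (length(objs) == 1L && !inherits(objs[[1L]], c("parcel_map", "effect_matrix",
      "feature_panel", "profile_set", "connectivity_matrix")))
    objs <- objs[[1L]]
  if (!length(objs)) stopf("no sources to align")
  id_sets <- lapply(objs, function(o) o$meta$region_id)
  common <- Reduce(intersect, id_sets)
  if (!length(common)) stopf("sources share no regions")
  common <- id_sets[[1L]][id_sets[[1L]] %in% common]  # first input's order
  out <- lapply(objs, function(o) {
    if (identical(o$meta$region_id, common)) o else restrict_obj(o, common)
  })
  attr(out, "n_common") <- length(common)
  out
}

#' Read / write parcellation metadata
#'
#' Tab-separated with columns `region_id`, `hemisphere`, `x`, `y`, `z`,
#' `community`, `hierarchy`.
#'
#' @param path file path.
#' @return [read_parcellation_meta()] returns a `parcellation_meta`.
#' @export
read_parcellation_meta <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = sniff_sep(path),
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("region_id", "hemisphere", "x", "y", "z", "community", "hierarchy")
  if (!all(need %in% names(df)))
    stopf("meta table must have columns: %s", paste(need, collapse = ", "))
  parcellation_meta(df$region_id, df$hemisphere,
                    cbind(df$x, df$y, df$z), df$community, df$hierarchy)
}

#' @param meta a [parcellation_meta()] to write.
#' @rdname read_parcellation_meta
#' @export
write_parcellation_meta <- function(meta, path) {
  fmt <- function(x) formatC(x, digits = 15, format = "g")
  lines <- c("region_id\themisphere\tx\ty\tz\tcommunity\thierarchy",
             paste(meta$region_id, meta$hemisphere,
                   fmt(meta$centroid[, 1L]), fmt(meta$centroid[, 2L]),
                   fmt(meta$centroid[, 3L]),
                   as.character(meta$community), as.character(meta$hierarchy),
                   sep = "\t"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
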