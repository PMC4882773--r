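#' Build a region adjacency map
#'
#' Constructs the symmetric, binary (0/1 weight) adjacency structure that
#' underlies every intrinsic CAR term in the model. Edges are deduplicated and
#' stored as unordered pairs; region order is the declared order of `regions`
#' and fixes the indexing of all vectorized quantities downstream.
#'
#' @param regions character vector of unique region labels.
#' @param edges two-column matrix or data frame of region label pairs (one row
#'   per edge), or `NULL` for an edgeless map.
#' @return An object of class `region_map`: list with elements `regions`,
#'   `edges` (integer index pairs, lower index first), `n_neighbors` (named),
#'   `components` (connected-component id per region) and `n_components`.
#'   Isolated regions are permitted but raise a warning.
#' @examples
#' m <- region_map(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
#' m$n_neighbors  # A:1 B:2 C:1
#' @export
region_map <- function(regions, edges = NULL) {
  regions <- as.character(regions)
  if (length(regions) < 1L) stop("at least one region is required")
  if (anyDuplicated(regions))
    stop("duplicate region labels: ",
         paste(unique(regions[duplicated(regions)]), collapse = ", "))
  R <- length(regions)

  if (is.null(edges) || !length(edges)) {
    em <- matrix(integer(0), ncol = 2)
  } else {
    if (is.data.frame(edges)) edges <- as.matrix(edges)
    if (!is.matrix(edges)) edges <- matrix(as.character(edges), ncol = 2, byrow = TRUE)
    edges <- matrix(as.character(edges), ncol = 2)
    unknown <- setdiff(c(edges), regions)
    if (length(unknown))
      stop("unknown region label(s) in edges: ", paste(unknown, collapse = ", "))
    if (any(edges[, 1] == edges[, 2]))
      stop("self-edges are not allowed (", edges[edges[, 1] == edges[, 2], 1][1], ")")
    a <- match(edges[, 1], regions)
    b <- match(edges[, 2], regions)
    lo <- pmin(a, b)
    hi <- pmax(a, b)
    keep <- !duplicated(paste(lo, hi))
    em <- cbind(lo[keep], hi[keep])
  }

  nn <- tabulate(c(em), nbins = R)
  names(nn) <- regions
  if (R > 1L && any(nn == 0L))
    warning("isolated region(s) with no neighbors: ",
            paste(regions[nn == 0L], collapse = ", "))

  # connected components by breadth-first search
  adj <- rep(list(integer(0)), R)
  for (e in seq_len(nrow(em))) {
    adj[[em[e, 1]]] <- c(adj[[em[e, 1]]], em[e, 2])
    adj[[em[e, 2]]] <- c(adj[[em[e, 2]]], em[e, 1])
  }
  comp <- integer(R)
  nc <- 0L
  for (s in seq_len(R)) {
    if (comp[s] > 0L) next
    nc <- nc + 1L
    queue <- s
    comp[s] <- nc
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      for (w in adj[[v]]) {
        if (comp[w] == 0L) {
          comp[w] <- nc
          queue <- c(queue, w)
        }
      }
    }
  }

  structure(list(regions = regions, edges = em, n_neighbors = nn,
                 components = comp, n_components = nc),
            class = "region_map")
}

#' @export
print.region_map <- function(x, ...) {
  cat("region_map:", length(x$regions), "regions,", nrow(x$edges), "edges,",
      x$n_components, "connected component(s)\n")
  cat("  regions:", paste(x$regions, collapse = ", "), "\n")
  invisible(x)
}

#' Read an adjacency edge list from a plain-text file
#'
#' The format is one edge per line, two whitespace-separated region labels;
#' lines starting with `#` are comments; a line with a single label declares
#' an isolated region. Region order follows first appearance in the file.
#'
#' @param path path to the edge-list file.
#' @return a [region_map].
#' @seealso [zhejiang_map()] for the bundled 11-prefecture fixture.
#' @export
read_adjacency <- function(path) {
  if (!file.exists(path)) stop("adjacency file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("adjacency file contains no edges: ", path)
  toks <- strsplit(lines, "[[:space:]]+")
  bad <- which(!vapply(toks, length, 1L) %in% c(1L, 2L))
  if (length(bad))
    stop("malformed adjacency line(s): ", paste(bad, collapse = ", "))
  regions <- unique(unlist(toks))
  edges <- do.call(rbind, toks[vapply(toks, length, 1L) == 2L])
  region_map(regions, edges)
}

#' The 11-prefecture Zhejiang adjacency fixture
#'
#' Adjacency of the 11 prefecture-level cities of Zhejiang Province read off
#' the public administrative map. The island prefecture Zhoushan has a single
#' neighbor (Ningbo); every other city has at least two.
#'
#' @return a [region_map] with 11 regions.
#' @export
zhejiang_map <- function() {
  suppressWarnings(
    read_adjacency(system.file("extdata", "zhejiang11.adj", package = "spscm"))
  )
}

#' Dense graph Laplacian of a region map
#'
#' Used by the synthetic generator to draw intrinsic CAR fields; also a
#' convenient cross-check for [car_quadratic_form()] since the pairwise
#' difference form equals `t(v) %*% L %*% v`.
#'
#' @param map a [region_map].
#' @return symmetric R x R matrix with region dimnames.
#' @export
laplacian <- function(map) {
  stopifnot(inherits(map, "region_map"))
  R <- length(map$regions)
  L <- matrix(0, R, R, dimnames = list(map$regions, map$regions))
  for (e in seq_len(nrow(map$edges))) {
    i <- map$edges[e, 1]
    j <- map$edges[e, 2]
    L[i, j] <- L[i, j] - 1
    L[j, i] <- L[j, i] - 1
    L[i, i] <- L[i, i] + 1
    L[j, j] <- L[j, j] + 1
  }
  L
}

#' Pairwise-difference CAR quadratic form
#'
#' Computes `sum over unordered neighbor pairs (i, j) of (v_i - v_j)^2`, the
#' quadratic form inside every intrinsic CAR log-density. It is invariant to
#' adding a constant to all values (the intrinsic improperness) and zero iff
#' the values are constant on each connected component.
#'
#' @param values numeric vector of one value per region, either in map order
#'   or named by region label.
#' @param map a [region_map].
#' @return a nonnegative scalar.
#' @export
car_quadratic_form <- function(values, map) {
  stopifnot(inherits(map, "region_map"))
  R <- length(map$regions)
  if (!is.null(names(values))) {
    miss <- setdiff(map$regions, names(values))
    if (length(miss))
      stop("missing value for region(s): ", paste(miss, collapse = ", "))
    values <- values[map$regions]
  }
  if (length(values) != R)
    stop("'values' must supply one value per region (need ", R, ", got ",
         length(values), ")")
  if (anyNA(values)) stop("missing region value in 'values'")
  if (!nrow(map$edges)) return(0)
  d <- values[map$edges[, 1]] - values[map$edges[, 2]]
  sum(d * d)
}

#' Expected counts by internal standardization
#'
#' For each gender the pooled crude rate `sum(O)/sum(n)` is applied to every
#' region's denominator, so per gender the expected counts conserve the
#' observed total exactly: `sum(E) = sum(O)`. This is the internal (within
#' study population) standardization behind the standardized prevalence ratio.
#'
#' @param data an [scm_data] object, or a list with 2 x R matrices `O` and `n`
#'   (rows male, female).
#' @return an object of class `standardized_counts`: list with matrices
#'   `observed` and `expected`.
#' @export
expected_counts <- function(data) {
  O <- data$O
  n <- data$n
  stopifnot(is.matrix(O), is.matrix(n), all(dim(O) == dim(n)))
  if (any(n < 0)) stop("denominators must be nonnegative")
  if (any(O > n)) stop("observed counts exceed denominators")
  E <- O * NA_real_
  for (j in 1:2) {
    tot_n <- sum(n[j, ])
    if (tot_n <= 0)
      stop("zero total denominator for gender '", GENDERS[j], "'")
    E[j, ] <- n[j, ] * sum(O[j, ]) / tot_n
  }
  structure(list(observed = O, expected = E), class = "standardized_counts")
}

#' Standardized prevalence ratio
#'
#' `SPR[j, i] = O[j, i] / E[j, i]`, the ratio of observed to internally
#' standardized expected counts: the maximum-likelihood regional relative-risk
#' estimate, unstable for small denominators. Per gender the expected-count
#' weighted mean SPR is 1 (mass conservation).
#'
#' @param counts a `standardized_counts` object from [expected_counts()].
#' @return 2 x R matrix of SPR values.
#' @export
spr <- function(counts) {
  stopifnot(inherits(counts, "standardized_counts"))
  E <- counts$expected
  if (any(E <= 0)) {
    bad <- which(E <= 0, arr.ind = TRUE)
    lab <- colnames(E)[bad[1, 2]]
    if (is.null(lab)) lab <- bad[1, 2]
    stop("expected count is zero for region ", lab,
         " (gender ", GENDERS[bad[1, 1]], "); SPR undefined")
  }
  counts$observed / E
}
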