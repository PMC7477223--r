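# Latent space Z, the generative-model interface G: Z -> X, a toy linear
# generator, and programmatic category assignment by projection sign.

#' Sample latent vectors from a standard multivariate normal
#'
#' Draws `n` i.i.d. latent vectors from N(0, I_m), the sampling distribution
#' used to obtain a fair, representative coverage of a generative model's
#' latent space (default dimensionality 512).
#'
#' @param n Number of vectors to draw (rows).
#' @param m Latent dimensionality (columns); default 512.
#' @param seed Optional integer seed; when given, sampling is reproducible
#'   and the caller's RNG state is left untouched.
#' @param ids Optional character vector of row identifiers; defaults to
#'   `z00001, z00002, ...`.
#' @return A `latent_batch`: an `n x m` numeric matrix with row names set to
#'   the vector ids and attribute `m`.
#' @examples
#' zb <- sample_latents(5, m = 8, seed = 1)
#' dim(zb)
#' @export
sample_latents <- function(n, m = 512, seed = NULL, ids = NULL) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop("`n` must be a positive integer", call. = FALSE)
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 1)
    stop("`m` must be a positive integer", call. = FALSE)
  n <- as.integer(n); m <- as.integer(m)
  draw <- function() matrix(stats::rnorm(n * m), nrow = n, ncol = m)
  x <- if (is.null(seed)) draw() else with_seed(seed, draw())
  if (is.null(ids)) ids <- sprintf("z%05d", seq_len(n))
  if (length(ids) != n) stop("`ids` must have length n", call. = FALSE)
  rownames(x) <- ids
  latent_batch(x)
}

#' Construct a latent batch from a numeric matrix
#'
#' @param x Numeric matrix, one latent vector per row; all entries finite.
#' @return The matrix with class `latent_batch` and attribute `m`.
#' @export
latent_batch <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x) || nrow(x) < 1L)
    stop("a latent batch needs at least one numeric row", call. = FALSE)
  if (!all(is.finite(x)))
    stop("latent vectors must be finite", call. = FALSE)
  if (is.null(rownames(x))) rownames(x) <- sprintf("z%05d", seq_len(nrow(x)))
  structure(x, m = ncol(x), class = c("latent_batch", class(matrix())))
}

#' @export
print.latent_batch <- function(x, ...) {
  cat(sprintf("<latent_batch> %d vectors, m = %d\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Specify a toy linear generative model
#'
#' A desk-scale generator G mapping a latent vector to `k` named scalar
#' attributes via a `k x m` projection matrix with unit-norm rows. It stands
#' behind the same `G: Z -> X` interface that an external image generator
#' would occupy, but its output is directly machine-checkable.
#'
#' @param projection Numeric `k x m` matrix; each row is normalised to unit
#'   Euclidean norm.
#' @param attributes Character vector of `k` attribute names.
#' @return A `generator_spec` object (`kind = "toy-attribute"`).
#' @export
toy_generator <- function(projection, attributes = NULL) {
  projection <- as.matrix(projection)
  if (!is.numeric(projection) || !all(is.finite(projection)))
    stop("`projection` must be a finite numeric matrix", call. = FALSE)
  nrm <- sqrt(rowSums(projection^2))
  if (any(nrm == 0))
    stop("projection rows must be non-zero", call. = FALSE)
  projection <- projection / nrm
  if (is.null(attributes)) attributes <- sprintf("attr%d", seq_len(nrow(projection)))
  if (length(attributes) != nrow(projection))
    stop("one attribute name per projection row is required", call. = FALSE)
  rownames(projection) <- attributes
  structure(list(kind = "toy-attribute", m = ncol(projection),
                 projection = projection, attributes = attributes),
            class = "generator_spec")
}

#' @export
print.generator_spec <- function(x, ...) {
  cat(sprintf("<generator_spec> kind = %s, m = %d, attributes: %s\n",
              x$kind, x$m, paste(x$attributes, collapse = ", ")))
  invisible(x)
}

#' Generate attribute values from a latent vector
#'
#' Applies the toy generator: `G(z) = P z`, a deterministic linear map from
#' the latent space to named attributes.
#'
#' @param z Numeric latent vector of length `spec$m`, or a `latent_batch`.
#' @param spec A `generator_spec` of kind `"toy-attribute"`.
#' @return Named numeric vector of attributes (or a matrix for a batch).
#' @export
toy_generate <- function(z, spec) {
  if (!inherits(spec, "generator_spec") || spec$kind != "toy-attribute")
    stop("`spec` must be a toy-attribute generator_spec", call. = FALSE)
  if (is.matrix(z)) {
    if (ncol(z) != spec$m) stop("latent dimension mismatch", call. = FALSE)
    out <- z %*% t(spec$projection)
    colnames(out) <- spec$attributes
    return(out)
  }
  if (length(z) != spec$m) stop("latent dimension mismatch", call. = FALSE)
  drop(spec$projection %*% z)
}

#' Define a perceptual category by a direction in latent space
#'
#' Category membership replaces human curation of stimuli: a latent vector
#' `z` is relevant for the task when its projection on the unit direction
#' `d` exceeds the threshold `t`. The complementary category (the "reverse
#' task", e.g. old vs young) is the same direction negated.
#'
#' @param name Task name (e.g. `"young"`).
#' @param d Numeric direction vector; normalised to unit norm.
#' @param threshold Scalar decision threshold on the projection; default 0
#'   (a symmetric split of the latent distribution).
#' @param reverse Name of the complementary task; default `"not <name>"`.
#' @return A `category_direction` object.
#' @export
category_direction <- function(name, d, threshold = 0, reverse = paste0("not ", name)) {
  d <- as.numeric(d)
  if (!all(is.finite(d)) || sqrt(sum(d^2)) == 0)
    stop("`d` must be a finite non-zero vector", call. = FALSE)
  structure(list(name = name, d = d / sqrt(sum(d^2)),
                 threshold = threshold, reverse = reverse),
            class = "category_direction")
}

#' Reverse a category direction
#'
#' @param dir A `category_direction`.
#' @return The complementary `category_direction` (negated direction,
#'   negated threshold, names swapped).
#' @export
reverse_direction <- function(dir) {
  stopifnot(inherits(dir, "category_direction"))
  category_direction(dir$reverse, -dir$d, -dir$threshold, reverse = dir$name)
}

#' Assign a-priori relevance labels by projection sign
#'
#' A latent vector is `"relevant"` for a task when `d . z > t` (strictly);
#' ties fall to `"irrelevant"`. Under the reversed direction every
#' non-tied vector flips category, mirroring complementary task pairs.
#'
#' @param z A latent vector or `latent_batch`.
#' @param dir A `category_direction` whose `d` has the same length as the
#'   latent vectors.
#' @return Character vector of `"relevant"` / `"irrelevant"`, one per vector.
#' @export
assign_relevance <- function(z, dir) {
  stopifnot(inherits(dir, "category_direction"))
  zm <- if (is.matrix(z)) z else matrix(z, nrow = 1)
  if (ncol(zm) != length(dir$d))
    stop("latent dimension does not match the category direction", call. = FALSE)
  proj <- drop(zm %*% dir$d)
  ifelse(proj > dir$threshold, "relevant", "irrelevant")
}

#' Default task set: complementary perceptual category pairs
#'
#' Builds the eight facial-attribute recognition tasks used throughout the
#' package as four reverse pairs (male/female, young/old, smile/no smile,
#' blond/dark), each pair sharing one latent direction with opposite signs.
#' Directions default to the first standard basis vectors, so the pairs are
#' mutually orthogonal.
#'
#' @param m Latent dimensionality.
#' @param pairs Character vector `"task|reverse"`; one latent direction per
#'   pair.
#' @param directions Optional numeric matrix (one unit row per pair)
#'   overriding the default basis directions.
#' @return Named list of `category_direction` objects (both members of every
#'   pair).
#' @export
default_tasks <- function(m = 512,
                          pairs = c("male|female", "young|old",
                                    "smile|no smile", "blond|dark"),
                          directions = NULL) {
  if (length(pairs) > m)
    stop("need at least one latent dimension per task pair", call. = FALSE)
  if (is.null(directions)) {
    directions <- diag(1, nrow = length(pairs), ncol = m)
  }
  out <- list()
  for (i in seq_along(pairs)) {
    nm <- strsplit(pairs[[i]], "|", fixed = TRUE)[[1]]
    if (length(nm) != 2) stop("pairs must be given as 'task|reverse'", call. = FALSE)
    fwd <- category_direction(nm[1], directions[i, ], reverse = nm[2])
    out[[nm[1]]] <- fwd
    out[[nm[2]]] <- reverse_direction(fwd)
  }
  out
}

#' Reverse-task lookup table for a task list
#'
#' @param tasks Named list of `category_direction` objects.
#' @return Named character vector mapping each task to its reverse task.
#' @export
reverse_pairs <- function(tasks) {
  vapply(tasks, function(d) d$reverse, character(1))
}

#' Write a latent batch as delimited text with a JSON sidecar
#'
#' The matrix goes to `path` as tab-separated values (one row per vector, no
#' header); dimensionality, ids and an optional seed go to `<path>.json`.
#'
#' @param batch A `latent_batch`.
#' @param path Output file path.
#' @param seed Optional seed to record in the sidecar.
#' @param directions Optional named list of `category_direction` objects to
#'   persist alongside the batch.
#' @return `path`, invisibly.
#' @export
write_latents <- function(batch, path, seed = NULL, directions = NULL) {
  stopifnot(inherits(batch, "latent_batch"))
  utils::write.table(unclass(batch), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  meta <- list(m = ncol(batch), n = nrow(batch), ids = rownames(batch))
  if (!is.null(seed)) meta$seed <- seed
  if (!is.null(directions)) {
    meta$directions <- lapply(directions, function(d)
      list(name = d$name, d = d$d, threshold = d$threshold, reverse = d$reverse))
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a latent batch written by [write_latents()]
#'
#' @param path Path previously passed to [write_latents()].
#' @return A `latent_batch`; any persisted category directions are attached
#'   as attribute `"directions"`.
#' @export
read_latents <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  x <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(x) <- list(meta$ids, NULL)
  if (ncol(x) != meta$m)
    stop("latent file does not match its sidecar dimensionality", call. = FALSE)
  out <- latent_batch(x)
  if (!is.null(meta$directions)) {
    dirs <- lapply(meta$directions, function(d)
      category_direction(d$name, d$d, d$threshold, d$reverse))
    attr(out, "directions") <- dirs
  }
  out
}

#' Cosine similarity between two vectors
#'
#' The convergence metric used to compare an intention estimate with the
#' true category direction.
#'
#' @param a,b Numeric vectors of equal length.
#' @return Scalar in `[-1, 1]`; `NA` if either vector is all-zero.
#' @export
cosine_similarity <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
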