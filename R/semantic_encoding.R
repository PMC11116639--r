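#' Serialize a per-minute MFCC vector as a sentence
#'
#' Renders the coefficients in a bracketed, comma-separated, fixed-precision
#' decimal format, e.g. `"[1.0000, 2.0000, 3.0000]"`. The rendering is
#' deterministic, locale-independent, and round-trip parseable:
#' `parse_sentence(serialize_minute(x))` equals `x` within
#' `10^-precision / 2`.
#'
#' @param coeffs Finite numeric vector (one minute's MFCC).
#' @param precision Decimal places (default 4).
#' @return A single string.
#' @export
serialize_minute <- function(coeffs, precision = 4L) {
  if (!all(is.finite(coeffs)))
    stop("cannot serialize non-finite coefficient", call. = FALSE)
  paste0("[", paste(formatC(coeffs, format = "f", digits = precision),
                    collapse = ", "), "]")
}

#' @rdname serialize_minute
#' @param text A sentence produced by [serialize_minute].
#' @export
parse_sentence <- function(text) {
  inner <- gsub("^\\s*\\[|\\]\\s*$", "", text)
  vals <- as.numeric(strsplit(inner, ",")[[1]])
  if (anyNA(vals)) stop("unparseable sentence: ", text, call. = FALSE)
  vals
}

#' Construct a sentence encoder backend
#'
#' Two backends share one interface. `"deterministic_fallback"` (the working
#' default, requiring no network or model weights) parses the numbers out of
#' the sentence, applies a seeded random projection, and squashes with
#' `tanh`: the projection matrix `P` (`dim x n_inputs`) is filled
#' column-major with standard-normal draws from R's default generator seeded
#' with `seed`, and the output is `tanh(P %*% v / sqrt(n_inputs))`. The
#' same (text, backend, seed) always yields the same vector.
#'
#' `"pretrained_biomedical_lm"` is the interface slot for a pretrained
#' biomedical sentence encoder (first-token pooling by default, mean pooling
#' via `pooling = "mean"`); it requires model weights on disk via
#' `weights_path` and a user-supplied `encode_fn(texts) -> matrix`. Without
#' them it fails loudly — never a silent substitution — advising the
#' fallback.
#'
#' @param name `"deterministic_fallback"` or `"pretrained_biomedical_lm"`.
#' @param dim Output dimension `d_s`.
#' @param seed Integer seed (fallback projection).
#' @param n_inputs Expected number of serialized coefficients (default 13).
#' @param pooling `"first_token"` or `"mean"` (pretrained backend only).
#' @param weights_path,encode_fn Pretrained backend plumbing.
#' @return An object of class `encoder_backend`.
#' @export
encoder_backend <- function(name = "deterministic_fallback", dim = 8L,
                            seed = 1L, n_inputs = 13L,
                            pooling = "first_token",
                            weights_path = NULL, encode_fn = NULL) {
  name <- match.arg(name, c("deterministic_fallback",
                            "pretrained_biomedical_lm"))
  b <- structure(list(name = name, dim = as.integer(dim),
                      seed = as.integer(seed), n_inputs = as.integer(n_inputs),
                      pooling = match.arg(pooling, c("first_token", "mean")),
                      weights_path = weights_path, encode_fn = encode_fn),
                 class = "encoder_backend")
  if (name == "deterministic_fallback")
    b$projection <- fallback_projection(b$dim, b$n_inputs, b$seed)
  b
}

# The documented fallback projection: dim x n_inputs standard-normal matrix,
# filled column-major from R's default RNG at the given seed. The global RNG
# state is left untouched.
fallback_projection <- function(dim, n_inputs, seed) {
  with_local_rng(seed, matrix(stats::rnorm(dim * n_inputs), nrow = dim))
}

# Run expr under set.seed(seed) without disturbing the caller's RNG stream.
with_local_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Encode a sentence into a semantic vector
#'
#' @param text Sentence string from [serialize_minute].
#' @param backend An [encoder_backend].
#' @return Numeric vector of length `backend$dim`.
#' @export
encode <- function(text, backend) {
  stopifnot(inherits(backend, "encoder_backend"))
  if (backend$name == "pretrained_biomedical_lm") {
    if (is.null(backend$encode_fn) || is.null(backend$weights_path) ||
        !file.exists(backend$weights_path))
      stop("pretrained biomedical encoder unavailable: no weights/encoder ",
           "function on disk. Use encoder_backend(\"deterministic_fallback\") ",
           "for a download-free deterministic encoder.", call. = FALSE)
    v <- backend$encode_fn(text)
    return(as.numeric(v)[seq_len(backend$dim)])
  }
  v <- parse_sentence(text)
  if (length(v) != backend$n_inputs)
    stop("sentence encodes ", length(v), " values; backend expects ",
         backend$n_inputs, call. = FALSE)
  as.numeric(tanh(backend$projection %*% v / sqrt(backend$n_inputs)))
}

#' Encode every minute of a night
#'
#' Row `t` of the result is `encode(serialize_minute(C_t))`; minutes are
#' independent (permuting input rows permutes output rows identically).
#'
#' @param mfcc_matrix `T x L` per-minute MFCC matrix from [minute_mfcc].
#' @param backend An [encoder_backend].
#' @param precision Serialization precision (decimal places).
#' @return `T x d_s` semantic matrix (columns `s1..s<d_s>`).
#' @export
encode_night <- function(mfcc_matrix, backend, precision = 4L) {
  if (!is.matrix(mfcc_matrix) || nrow(mfcc_matrix) == 0L)
    stop("mfcc_matrix must be a nonempty matrix", call. = FALSE)
  out <- matrix(NA_real_, nrow(mfcc_matrix), backend$dim)
  for (t in seq_len(nrow(mfcc_matrix))) {
    out[t, ] <- tryCatch(
      encode(serialize_minute(mfcc_matrix[t, ], precision), backend),
      error = function(e) stop("minute ", t, ": ", conditionMessage(e),
                               call. = FALSE))
  }
  rownames(out) <- rownames(mfcc_matrix)
  colnames(out) <- paste0("s", seq_len(backend$dim))
  out
}
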