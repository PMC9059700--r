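# Majority-rule voting across prediction sources (e.g. three architectures,
# or three preprocessing variants feeding one architecture).

#' Aligned set of binary vote matrices
#'
#' @param ... binary label matrices (records x labels) with identical shapes
#'   and row order; row names, when present, must agree.
#' @param k required number of members (default 3; must be odd so no cell
#'   can tie).
#' @return object of class `vote_set` (list of matrices).
#' @export
vote_set <- function(..., k = 3L) {
  members <- list(...)
  if (length(members) == 1L && is.list(members[[1]]) &&
      !is.matrix(members[[1]])) members <- members[[1]]
  if (k %% 2L == 0L) stop("k must be odd so that no per-cell tie is possible")
  if (length(members) != k)
    stop("expected exactly ", k, " members, got ", length(members))
  ref <- members[[1]]
  for (m in members) {
    if (!all(dim(m) == dim(ref))) stop("member shape mismatch")
    if (!all(m %in% c(0, 1))) stop("members must be binary matrices")
    if (!is.null(rownames(m)) && !is.null(rownames(ref)) &&
        !identical(rownames(m), rownames(ref)))
      stop("member record ids are not aligned")
  }
  structure(members, class = "vote_set")
}

#' Majority-rule vote over binary predictions
#'
#' A cell of the output is 1 exactly when the majority of members (at least
#' 2 of 3 with the default) vote 1 -- equivalently, when the member sum
#' reaches `(k+1)/2`. Permutation of members does not change the result.
#'
#' @param votes a [vote_set()], or 3 matrices given directly.
#' @param ... additional matrices when `votes` is a single matrix.
#' @return binary matrix of majority decisions, dimnames of the first
#'   member.
#' @export
majority_vote <- function(votes, ...) {
  if (!inherits(votes, "vote_set"))
    votes <- vote_set(c(list(votes), list(...)), k = 1L + length(list(...)))
  k <- length(votes)
  s <- Reduce(`+`, votes)
  out <- ifelse(s >= (k + 1) / 2, 1L, 0L)
  dimnames(out) <- dimnames(votes[[1]])
  out
}
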