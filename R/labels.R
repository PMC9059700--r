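# ODIR-style multi-label plumbing: 8 binary flags in the fixed order
# N (normal), D (diabetic retinopathy), G (glaucoma), C (cataract),
# A (age-related macular degeneration), H (hypertensive retinopathy),
# M (pathological myopia), O (other abnormalities).

lv_classes <- c("N", "D", "G", "C", "A", "H", "M", "O")

#' Construct an 8-bit label vector
#'
#' @param x class letters to set (e.g. `c("D","C")`), an 8-char bitstring, or
#'   a numeric/integer vector of 8 flags.
#' @return named integer vector of 8 flags in order N,D,G,C,A,H,M,O, class
#'   `label_vector`.
#' @export
label_vector <- function(x = character(0)) {
  bits <- stats::setNames(integer(8), lv_classes)
  if (is.character(x) && length(x) == 1L && nchar(x) == 8L && grepl("^[01]{8}$", x)) {
    bits[] <- as.integer(strsplit(x, "")[[1]])
  } else if (is.character(x)) {
    bad <- setdiff(x, lv_classes)
    if (length(bad)) stop("unknown classes: ", paste(bad, collapse = ", "))
    bits[x] <- 1L
  } else {
    if (length(x) != 8L || !all(x %in% c(0, 1)))
      stop("numeric input must be 8 binary flags")
    bits[] <- as.integer(x)
  }
  structure(bits, class = "label_vector")
}

#' Serialize a label vector as an 8-character bitstring
#' @param label a [label_vector()] (or 8 binary flags).
#' @return single string such as `"00010000"`.
#' @export
as_bitstring <- function(label) paste(as.integer(label), collapse = "")

#' @export
print.label_vector <- function(x, ...) {
  on <- lv_classes[x == 1L]
  cat(as_bitstring(x), if (length(on)) paste0(" (", paste(on, collapse = "+"), ")"),
      "\n", sep = "")
  invisible(x)
}

#' Default diagnostic-keyword map
#'
#' Ordered phrase patterns matched case-insensitively as substrings of each
#' comma-separated phrase in a diagnostic string. Phrases matching no pattern
#' fall through to the catch-all class O (or raise an error in strict mode).
#'
#' @return data frame with columns `pattern`, `class`.
#' @export
default_keyword_map <- function() {
  data.frame(
    pattern = c("normal fundus",
                "diabetic retinopathy", "non proliferative retinopathy",
                "proliferative retinopathy",
                "glaucoma",
                "cataract",
                "macular degeneration",
                "hypertensive retinopathy",
                "myopia",
                "epiretinal membrane", "macular hole", "pigmentation",
                "drusen", "vitreous degeneration"),
    class = c("N", "D", "D", "D", "G", "C", "A", "H", "M",
              "O", "O", "O", "O", "O"),
    stringsAsFactors = FALSE
  )
}

#' Map a diagnostic keyword string to a per-eye label vector
#'
#' The text is split on commas; each phrase is matched (case-insensitive
#' substring) against the ordered patterns of `map`, and the bit of every
#' matched class is set. The phrase `normal fundus` sets the Normal bit of
#' the per-eye vector.
#'
#' @param text non-empty keyword string, phrases separated by commas.
#' @param map keyword map as from [default_keyword_map()].
#' @param strict if `TRUE`, a phrase matching no pattern raises an error;
#'   otherwise it maps to the catch-all class O.
#' @return a [label_vector()].
#' @export
keywords_to_label <- function(text, map = default_keyword_map(), strict = FALSE) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop("`text` must be a non-empty keyword string")
  phrases <- trimws(strsplit(tolower(text), ",", fixed = TRUE)[[1]])
  phrases <- phrases[nzchar(phrases)]
  classes <- character(0)
  for (ph in phrases) {
    hit <- vapply(tolower(map$pattern), function(p) grepl(p, ph, fixed = TRUE),
                  logical(1))
    if (any(hit)) classes <- c(classes, map$class[hit])
    else if (strict) stop("unknown keyword phrase: '", ph, "'")
    else classes <- c(classes, "O")
  }
  label_vector(unique(classes))
}

is_normal_only <- function(label)
  label[["N"]] == 1L && sum(as.integer(label)) == 1L

#' Combine per-eye labels into a patient label, with verification
#'
#' Disease bits are the bitwise union of the two eyes. The Normal bit is kept
#' only when both eyes are Normal-only; a normal finding in one eye is
#' ignored when the other eye carries disease.
#'
#' @param left,right per-eye [label_vector()]s.
#' @param declared optional declared patient label to verify against.
#' @return list with `label` (the combined [label_vector()]) and `verified`
#'   (`TRUE`/`FALSE` when `declared` is given, `NA` otherwise).
#' @export
union_and_verify <- function(left, right, declared = NULL) {
  l <- as.integer(left); r <- as.integer(right)
  stopifnot(length(l) == 8L, length(r) == 8L)
  bits <- as.integer(l | r)
  bits[1] <- as.integer(is_normal_only(label_vector(l)) &&
                        is_normal_only(label_vector(r)))
  out <- label_vector(bits)
  verified <- if (is.null(declared)) NA
              else identical(as.integer(out), as.integer(label_vector(
                if (is.character(declared)) declared else as.integer(declared))))
  list(label = out, verified = verified)
}

#' Relabel an ODIR-style manifest from its keyword strings
#'
#' Applies [keywords_to_label()] per eye and [union_and_verify()] per patient
#' against the manifest's `final_label` column. Mismatches are reported with
#' a warning, never silently overwritten.
#'
#' @param manifest data frame with columns `id`, `left_keywords`,
#'   `right_keywords` and optionally `final_label` (8-char bitstrings).
#' @param map,strict see [keywords_to_label()].
#' @return the manifest with added columns `left_label`, `right_label`,
#'   `union_label` (bitstrings) and logical `verified`.
#' @export
relabel_manifest <- function(manifest, map = default_keyword_map(),
                             strict = FALSE) {
  stopifnot(all(c("id", "left_keywords", "right_keywords") %in% names(manifest)))
  n <- nrow(manifest)
  left <- character(n); right <- character(n); uni <- character(n)
  ver <- rep(NA, n)
  has_final <- "final_label" %in% names(manifest)
  for (i in seq_len(n)) {
    ll <- keywords_to_label(manifest$left_keywords[i], map, strict)
    rl <- keywords_to_label(manifest$right_keywords[i], map, strict)
    u <- union_and_verify(ll, rl,
                          declared = if (has_final) manifest$final_label[i])
    left[i] <- as_bitstring(ll); right[i] <- as_bitstring(rl)
    uni[i] <- as_bitstring(u$label); ver[i] <- u$verified
  }
  if (has_final && any(!ver))
    warning(sum(!ver), " of ", n, " records failed label verification")
  manifest$left_label <- left
  manifest$right_label <- right
  manifest$union_label <- uni
  manifest$verified <- ver
  manifest
}

#' Aggregate per-eye prediction scores to the patient level
#'
#' Label-wise maximum of the two eyes' scores; with a single available eye
#' (other argument `NULL`) the present eye's scores pass through, supporting
#' single-visit screening.
#'
#' @param left_scores,right_scores numeric length-8 score vectors in \[0,1\]
#'   (either may be `NULL`).
#' @return length-8 numeric vector.
#' @export
aggregate_patient <- function(left_scores, right_scores) {
  if (is.null(left_scores) && is.null(right_scores))
    stop("at least one eye's scores must be given")
  chk <- function(s) {
    if (is.null(s)) return(NULL)
    if (length(s) != 8L) stop("score vectors must have length 8")
    if (any(s < 0 | s > 1)) stop("scores must lie in [0, 1]")
    s
  }
  l <- chk(left_scores); r <- chk(right_scores)
  if (is.null(l)) return(r)
  if (is.null(r)) return(l)
  pmax(l, r)
}

#' Binarize a DDR diabetic-retinopathy grade for screening
#'
#' Grade 0 is normal, grades 1--4 abnormal; grade 5 flags ungradable images,
#' which are excluded.
#'
#' @param grade integer vector with values in 0..5.
#' @return factor with levels normal, abnormal, excluded.
#' @export
map_ddr_binary <- function(grade) {
  if (any(!grade %in% 0:5)) stop("DDR grades must lie in 0..5")
  factor(ifelse(grade == 0, "normal", ifelse(grade == 5, "excluded", "abnormal")),
         levels = c("normal", "abnormal", "excluded"))
}

#' Screening score for normal-vs-abnormal decisions
#'
#' The binary screening score is one minus the predicted probability of the
#' Normal class.
#'
#' @param scores matrix of per-class scores (records x 8) or length-8 vector.
#' @return numeric vector of abnormality scores.
#' @export
ddr_screening_score <- function(scores) {
  if (is.matrix(scores)) 1 - scores[, 1] else 1 - scores[1]
}
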