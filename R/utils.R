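## internal validation helpers shared across modules

SEX_LEVELS <- c("male", "female")
GENOTYPE_LEVELS <- c("WT", "KO")

#' @noRd
.as_design <- function(design) {
  stopifnot(is.data.frame(design))
  need <- c("sample_id", "sex", "genotype")
  miss <- setdiff(need, names(design))
  if (length(miss))
    stop("design is missing column(s): ", paste(miss, collapse = ", "))
  design$sample_id <- as.character(design$sample_id)
  if (anyDuplicated(design$sample_id))
    stop("duplicated sample_id in design")
  if (!all(design$sex %in% SEX_LEVELS))
    stop("sex must be one of: ", paste(SEX_LEVELS, collapse = ", "))
  if (!all(design$genotype %in% GENOTYPE_LEVELS))
    stop("genotype must be one of: ", paste(GENOTYPE_LEVELS, collapse = ", "))
  design$sex <- factor(design$sex, levels = SEX_LEVELS)
  design$genotype <- factor(design$genotype, levels = GENOTYPE_LEVELS)
  if (!is.null(design$batch))
    design$batch <- factor(design$batch)
  design
}

#' @noRd
.check_expr <- function(expr, design = NULL) {
  stopifnot(is.matrix(expr), is.numeric(expr))
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix must carry probe row names and sample column names")
  if (anyDuplicated(rownames(expr))) stop("duplicated probe ids")
  if (anyDuplicated(colnames(expr))) stop("duplicated sample ids")
  if (!is.null(design)) {
    design <- .as_design(design)
    if (!setequal(colnames(expr), design$sample_id))
      stop("expression columns and design sample_id do not match")
    design <- design[match(colnames(expr), design$sample_id), , drop = FALSE]
  }
  invisible(design)
}

#' @noRd
.expr_scale <- function(expr) {
  sc <- attr(expr, "scale")
  if (is.null(sc)) NA_character_ else sc
}

#' @noRd
.set_scale <- function(expr, scale) {
  attr(expr, "scale") <- match.arg(scale, c("raw", "log2"))
  expr
}

## sex x genotype cell label per sample, fixed level order
#' @noRd
.group_of <- function(design) {
  factor(paste(design$sex, design$genotype, sep = "."),
         levels = as.vector(outer(SEX_LEVELS, GENOTYPE_LEVELS, paste, sep = ".")))
}

#' @noRd
.norm_symbol <- function(x) toupper(trimws(as.character(x)))
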