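#' Efficiency-corrected qPCR relative expression
#'
#' Expression of a target amplicon relative to a reference amplicon,
#' corrected for the amplification efficiency of each primer pair:
#' \deqn{e = E_{target}^{-Ct_{target}} / E_{ref}^{-Ct_{ref}}}
#' where E is the fold amplification per cycle (2 at perfect efficiency,
#' typically 1.8-2.1 from a standard curve) and Ct the threshold cycle.
#' One extra target cycle at E = 2 halves the result.
#'
#' @param E_target,E_ref amplification efficiencies (> 1).
#' @param Ct_target,Ct_ref threshold cycles (> 0).
#' @return Relative expression (positive scalar).
#' @export
relative_expression <- function(E_target, Ct_target, E_ref, Ct_ref) {
  vals <- c(E_target = E_target, Ct_target = Ct_target,
            E_ref = E_ref, Ct_ref = Ct_ref)
  if (any(!is.finite(vals))) stop("non-finite qPCR input", call. = FALSE)
  if (E_target <= 1 || E_ref <= 1) {
    stop("amplification efficiencies must exceed 1", call. = FALSE)
  }
  if (Ct_target <= 0 || Ct_ref <= 0) {
    stop("threshold cycles must be positive", call. = FALSE)
  }
  E_target^(-Ct_target) / E_ref^(-Ct_ref)
}

#' Summarize expression replicates as mean and SEM
#'
#' @param values numeric vector of per-replicate relative expression
#'   (independent RNA preparations); at least two, since the SEM is
#'   undefined for a single replicate.
#' @return list with `mean`, `sem` (sample SD / sqrt(n)) and `n`.
#' @export
summarize_replicates <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stop("SEM undefined for fewer than 2 replicates", call. = FALSE)
  if (any(!is.finite(values))) stop("non-finite replicate value", call. = FALSE)
  list(mean = mean(values), sem = stats::sd(values) / sqrt(n), n = n)
}

#' Relative-expression summary from a qPCR measurement table
#'
#' Input columns: `target`, `E_target`, `Ct_target`, `E_ref`, `Ct_ref`,
#' `replicate`.  Each row is converted with [relative_expression()] and
#' replicates are summarized per target.
#'
#' @param df data.frame of measurements (or a CSV path).
#' @return data.frame with columns target, mean, sem, n.
#' @export
qpcr_summary <- function(df) {
  if (is.character(df)) df <- read.csv(df, stringsAsFactors = FALSE)
  need <- c("target", "E_target", "Ct_target", "E_ref", "Ct_ref")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("qPCR table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  e <- mapply(relative_expression, df$E_target, df$Ct_target,
              df$E_ref, df$Ct_ref)
  out <- lapply(split(e, df$target), function(v) {
    s <- summarize_replicates(v)
    data.frame(mean = s$mean, sem = s$sem, n = s$n)
  })
  res <- do.call(rbind, out)
  data.frame(target = names(out), res, row.names = NULL,
             stringsAsFactors = FALSE)
}
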