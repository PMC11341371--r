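# broom-style tidiers for fitted objects.

#' Tidy a fine-tuned classifier
#'
#' @param x An `epi_classifier`.
#' @param ... Unused.
#' @return The per-epoch metric trace as a tibble.
#' @method tidy epi_classifier
#' @export
tidy.epi_classifier <- function(x, ...) x$trace

#' One-row summary of a fine-tuned classifier
#'
#' @param x An `epi_classifier`.
#' @param ... Unused.
#' @return Tibble: `best_epoch`, `auroc`, `aupr`, `f1`, `epochs`.
#' @method glance epi_classifier
#' @export
glance.epi_classifier <- function(x, ...) {
  b <- x$trace[x$trace$epoch == x$best_epoch, ]
  tibble(best_epoch = x$best_epoch, auroc = b$auroc, aupr = b$aupr,
         f1 = b$f1, epochs = nrow(x$trace))
}

#' Tidy a pre-training run
#'
#' @param x An `epi_pretrain`.
#' @param ... Unused.
#' @return The per-step loss trace.
#' @method tidy epi_pretrain
#' @export
tidy.epi_pretrain <- function(x, ...) x$trace

#' One-row summary of a pre-training run
#'
#' @param x An `epi_pretrain`.
#' @param ... Unused.
#' @return Tibble: `steps`, `initial_loss`, `final_loss`, `final_val_loss`.
#' @method glance epi_pretrain
#' @export
glance.epi_pretrain <- function(x, ...) {
  tibble(steps = x$steps_run,
         initial_loss = x$trace$loss[1L],
         final_loss = x$trace$loss[nrow(x$trace)],
         final_val_loss = x$trace$val_loss[nrow(x$trace)])
}

#' Tidy a domain-adversarial training run
#'
#' @param x An `epi_dann`.
#' @param ... Unused.
#' @return The per-step loss breakdown (`L_class`, `L_domain`,
#'   `L_total`, `lambda`).
#' @method tidy epi_dann
#' @export
tidy.epi_dann <- function(x, ...) x$trace

#' One-row summary of a domain-adversarial run
#'
#' @param x An `epi_dann`.
#' @param ... Unused.
#' @return Tibble: `steps`, `lambda`, final loss terms.
#' @method glance epi_dann
#' @export
glance.epi_dann <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  tibble(steps = nrow(x$trace), lambda = x$lambda,
         L_class = last$L_class, L_domain = last$L_domain, L_total = last$L_total)
}
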