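#' Read a 3C-qPCR quantity table
#'
#' Tab-separated with header: `fragment_id`, `distance_kb`, `condition`,
#' `replicate`, `quantity`. Quantities are qPCR-derived template amounts
#' from equal-input libraries (arbitrary units, >= 0).
#'
#' @param path TSV path.
#' @return A validated data.frame.
#' @export
read_three_c <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("fragment_id", "distance_kb", "condition", "replicate", "quantity")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("3C table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(df$quantity < 0)) stop("3C quantities must be >= 0")
  if (any(df$replicate < 1)) stop("replicate indices must be >= 1")
  df
}

#' Convert qPCR Ct values to relative template quantities
#'
#' Optional helper for tables that report Ct instead of quantity:
#' `quantity = 2^(-Ct) * scale`, assuming perfect doubling efficiency.
#'
#' @param ct Numeric Ct values.
#' @param scale Multiplicative scale (default 1e12, putting typical Ct
#'   ranges on a convenient unit scale).
#' @return Numeric quantities.
#' @export
ct_to_quantity <- function(ct, scale = 1e12) 2^(-ct) * scale

#' Normalize 3C interaction frequencies to a short-range ligation control
#'
#' Within each (condition, replicate), each fragment's interaction
#' frequency is its quantity as a percentage of the short-range control
#' fragment's quantity: `IF = quantity / quantity_control * 100`. The
#' control therefore normalizes to exactly 100% in every replicate, which
#' cancels cross-linking and ligation efficiency differences between
#' samples. Per-fragment means and SDs across replicates are then reported
#' per condition.
#'
#' @param measurements Data.frame as from [read_three_c()].
#' @param control_fragment `fragment_id` of the short-range ligation
#'   control; must be present with quantity > 0 in every replicate.
#' @return A list of class `interaction_profile` with `profile`
#'   (fragment_id, distance_kb, condition, mean_if, sd_if, n_rep),
#'   `replicate_if` (per-replicate IFs) and `control_fragment`.
#' @export
normalize_interaction <- function(measurements, control_fragment) {
  m <- measurements
  key <- interaction(m$condition, m$replicate, drop = TRUE)
  ctrl <- m$fragment_id == control_fragment
  reps <- split(seq_len(nrow(m)), key)
  out <- lapply(names(reps), function(k) {
    idx <- reps[[k]]
    ci <- idx[ctrl[idx]]
    if (!length(ci)) {
      stop("control fragment '", control_fragment,
           "' missing in replicate group ", k)
    }
    cq <- m$quantity[ci[1]]
    if (cq <= 0) stop("control fragment quantity is 0 in replicate group ",
                      k, ": cannot normalize")
    data.frame(fragment_id = m$fragment_id[idx],
               distance_kb = m$distance_kb[idx],
               condition = m$condition[idx],
               replicate = m$replicate[idx],
               interaction_freq = m$quantity[idx] / cq * 100,
               stringsAsFactors = FALSE)
  })
  rep_if <- do.call(rbind, out)
  # fragments missing from some replicate simply contribute fewer values
  frag_cond <- split(rep_if,
                     list(rep_if$fragment_id, rep_if$condition), drop = TRUE)
  n_rep_expected <- length(unique(paste(rep_if$condition, rep_if$replicate)))
  prof <- do.call(rbind, lapply(frag_cond, function(d) {
    data.frame(fragment_id = d$fragment_id[1],
               distance_kb = d$distance_kb[1],
               condition = d$condition[1],
               mean_if = mean(d$interaction_freq),
               sd_if = stats::sd(d$interaction_freq),
               n_rep = nrow(d), stringsAsFactors = FALSE)
  }))
  n_by_cond <- tapply(rep_if$replicate, rep_if$condition,
                      function(r) length(unique(r)))
  short <- prof$n_rep < n_by_cond[prof$condition]
  if (any(short)) {
    warning("fragment(s) missing in some replicate(s): ",
            paste(unique(prof$fragment_id[short]), collapse = ", "))
  }
  prof <- prof[order(prof$condition, prof$distance_kb, prof$fragment_id), ]
  rownames(prof) <- NULL
  structure(list(profile = prof, replicate_if = rep_if,
                 control_fragment = control_fragment),
            class = "interaction_profile")
}

#' @export
print.interaction_profile <- function(x, ...) {
  cat(sprintf("interaction_profile: %d fragments, %d condition(s), control '%s'\n",
              length(unique(x$profile$fragment_id)),
              length(unique(x$profile$condition)), x$control_fragment))
  print(x$profile, ...)
  invisible(x)
}

#' Compare interaction frequencies between two conditions
#'
#' Per fragment, the ratio of mean interaction frequencies
#' (`condition_pair[2] / condition_pair[1]`) and a two-sided t-test on the
#' replicate IFs (Welch). With fewer than 3 replicates in either condition
#' the ratio is still reported but the p-value is omitted with a warning;
#' zero-variance replicates yield an exact ratio and a degenerate-flagged,
#' `NA` p-value.
#'
#' @param profile An `interaction_profile` covering both conditions.
#' @param fragments Fragment ids of interest (default: all).
#' @param condition_pair Length-2 character (reference, treatment); default
#'   the two conditions present.
#' @return A data.frame: `fragment_id`, `mean_if_ref`, `mean_if_alt`,
#'   `ratio`, `p_value`, `degenerate`.
#' @export
compare_conditions <- function(profile, fragments = NULL,
                               condition_pair = NULL) {
  stopifnot(inherits(profile, "interaction_profile"))
  rif <- profile$replicate_if
  conds <- unique(rif$condition)
  if (is.null(condition_pair)) {
    if (length(conds) != 2) stop("specify condition_pair: found ",
                                 paste(conds, collapse = ", "))
    condition_pair <- conds
  }
  stopifnot(all(condition_pair %in% conds))
  if (is.null(fragments)) fragments <- unique(rif$fragment_id)
  warned <- FALSE
  out <- do.call(rbind, lapply(fragments, function(f) {
    a <- rif$interaction_freq[rif$fragment_id == f &
                                rif$condition == condition_pair[1]]
    b <- rif$interaction_freq[rif$fragment_id == f &
                                rif$condition == condition_pair[2]]
    ratio <- mean(b) / mean(a)
    degenerate <- FALSE
    p <- NA_real_
    if (length(a) < 3 || length(b) < 3) {
      if (!warned) {
        warning("fewer than 3 replicates for fragment '", f,
                "': ratio only, p-value omitted")
        warned <<- TRUE
      }
    } else if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      degenerate <- TRUE
    } else {
      p <- stats::t.test(b, a)$p.value
    }
    data.frame(fragment_id = f, mean_if_ref = mean(a), mean_if_alt = mean(b),
               ratio = ratio, p_value = p, degenerate = degenerate,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
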