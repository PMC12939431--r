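#' Match a called event table against a truth event log
#'
#' Greedy one-to-one matching within each (isolate, class, subtype,
#' chromosome) stratum: a called event matches a truth event when their
#' spans reciprocally overlap by at least `min_overlap` of each span (point
#' events such as SNVs therefore require positional identity). Returns
#' per-class and per-subtype precision/recall, the workhorse for simulation
#' benchmarking.
#'
#' @param truth data.frame with `isolate`, `class`, `subtype`, `chrom`,
#'   `start`, `end` (the simulator's true event log).
#' @param called an `EventTable`.
#' @param min_overlap minimum reciprocal overlap fraction (default 0.5).
#' @return list with data.frames `by_subtype` (matching within subtype) and
#'   `by_class` (matching within class, so a detected event with a flipped
#'   subtype still counts as found), each holding `n_truth`, `n_called`,
#'   `tp`, `precision`, `recall`, `f1`.
#' @export
match_event_tables <- function(truth, called, min_overlap = 0.5) {
  greedy_match <- function(tkey, ckey) {
    tp_t <- rep(FALSE, nrow(truth)); tp_c <- rep(FALSE, nrow(called))
    for (k in intersect(unique(tkey), unique(ckey))) {
      ti <- which(tkey == k); ci <- which(ckey == k)
      for (i in ti) {
        best <- 0; best_j <- NA_integer_
        for (j in ci[!tp_c[ci]]) {
          ov <- min(truth$end[i], called$end[j]) -
            max(truth$start[i], called$start[j])
          if (ov <= 0) next
          rec <- min(ov / (truth$end[i] - truth$start[i]),
                     ov / (called$end[j] - called$start[j]))
          if (rec >= min_overlap && rec > best) { best <- rec; best_j <- j }
        }
        if (!is.na(best_j)) { tp_t[i] <- TRUE; tp_c[best_j] <- TRUE }
      }
    }
    list(t = tp_t, c = tp_c)
  }
  summarize <- function(mm, t_sel, c_sel) {
    nt <- sum(t_sel); nc <- sum(c_sel); tp <- sum(mm$t & t_sel)
    prec <- if (nc) sum(mm$c & c_sel) / nc else NA_real_
    rec <- if (nt) tp / nt else NA_real_
    f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
      2 * prec * rec / (prec + rec) else NA_real_
    c(n_truth = nt, n_called = nc, tp = tp, precision = prec, recall = rec,
      f1 = f1)
  }
  m_sub <- greedy_match(
    paste(truth$isolate, truth$class, truth$subtype, truth$chrom, sep = "\r"),
    paste(called$isolate, called$class, called$subtype, called$chrom,
          sep = "\r"))
  m_cls <- greedy_match(
    paste(truth$isolate, truth$class, truth$chrom, sep = "\r"),
    paste(called$isolate, called$class, called$chrom, sep = "\r"))
  all_sub <- unique(rbind(truth[, c("class", "subtype")],
                          called[, c("class", "subtype")]))
  by_sub <- do.call(rbind, lapply(seq_len(nrow(all_sub)), function(r) {
    cl <- all_sub$class[r]; su <- all_sub$subtype[r]
    data.frame(class = cl, subtype = su, t(summarize(
      m_sub, truth$class == cl & truth$subtype == su,
      called$class == cl & called$subtype == su)),
      stringsAsFactors = FALSE)
  }))
  by_class <- do.call(rbind, lapply(unique(all_sub$class), function(cl)
    data.frame(class = cl, t(summarize(m_cls, truth$class == cl,
                                       called$class == cl)),
               stringsAsFactors = FALSE)))
  rownames(by_sub) <- rownames(by_class) <- NULL
  list(by_subtype = by_sub, by_class = by_class)
}
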