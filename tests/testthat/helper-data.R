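# shared fixtures, generated in code

# a moderately sized simulated dataset reused across test files
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_dataset(sim_config(n_genes = 400,
                                            n_control_probes = 800,
                                            seed = 42))
    }
    cache
  }
})

# minimal probe table builder: one gene, explicit offsets/signals, one day
make_probe_table <- function(gene = "gA", offsets, signals, day = 0,
                             replicate = 1) {
  data.frame(probe_id = sprintf("%s_p%02d", gene, seq_along(offsets)),
             gene_id = gene, offset_bp = offsets, day = day,
             replicate = replicate, signal = signals,
             stringsAsFactors = FALSE)
}

# control-probe table: n values per day drawn by the caller
make_control_table <- function(signal_by_day, replicate = 1) {
  do.call(rbind, lapply(names(signal_by_day), function(d) {
    s <- signal_by_day[[d]]
    data.frame(probe_id = sprintf("c%05d", seq_along(s)),
               gene_id = NA_character_, offset_bp = NA_integer_,
               day = as.numeric(d), replicate = replicate, signal = s,
               stringsAsFactors = FALSE)
  }))
}

# hand-built state matrix (bypasses calling) for transition tests
make_state_matrix <- function(gene, probes, states_by_day) {
  out <- do.call(rbind, lapply(names(states_by_day), function(d) {
    data.frame(gene_id = gene, probe_id = probes, offset_bp = NA_integer_,
               day = as.numeric(d), signal = NA_real_, p = NA_real_,
               q = NA_real_, acetylated = states_by_day[[d]],
               stringsAsFactors = FALSE)
  }))
  attr(out, "days") <- as.numeric(names(states_by_day))
  class(out) <- c("state_matrix", "data.frame")
  out
}

# independent brute-force running-sum enrichment oracle (plain loop)
oracle_es <- function(genes, scores, set, w = 1) {
  hits <- genes %in% set
  wts <- unname(abs(scores)^w)
  denom <- sum(wts[hits])
  cur <- 0
  best <- 0
  for (i in seq_along(genes)) {
    if (hits[i]) {
      cur <- cur + (if (denom > 0) wts[i] / denom else 1 / sum(hits))
    } else {
      cur <- cur - 1 / (length(genes) - sum(hits))
    }
    if (abs(cur) > abs(best)) best <- cur
  }
  best
}
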