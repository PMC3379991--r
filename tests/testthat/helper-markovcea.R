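# Shared fixtures for the test suite.  Everything is built in code.

# A hand-made transition schedule (single stream per transition).
make_schedule <- function(p_sp, p_sd, p_pd,
                          n = max(length(p_sp), length(p_sd),
                                  length(p_pd))) {
  structure(list(p_stable_prog = rep_len(p_sp, n),
                 p_stable_dead = rep_len(p_sd, n),
                 p_prog_dead = rep_len(p_pd, n),
                 cycles = as.integer(n), clipped = integer(0),
                 residual = numeric(n)),
            class = "transition_schedule")
}

# Base case fitted once per test file run (deterministic, ~0.1 s).
base_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- cea_model()
    cache
  }
})

# Parameters with every PSA distribution degenerate at its base value.
degenerate_params <- function() {
  p <- default_parameters()
  p$utilities$stable_dist <- dist_fixed(p$utilities$stable)
  p$utilities$progression_dist <- dist_fixed(p$utilities$progression)
  for (f in c("chemo_monthly_total", "pharmacy_prep", "progression_monthly",
              "mild_ae_monthly_antihistamine", "mild_ae_monthly_skin"))
    p$costs[[paste0(f, "_dist")]] <- dist_fixed(p$costs[[f]])
  cm <- cetuximab_monthly_cost(1, p$costs)
  cl <- cetuximab_monthly_cost(2, p$costs)
  p$costs$cetuximab_dose_month1_dist <- dist_fixed(cm$drug)
  p$costs$cetuximab_dose_later_dist <- dist_fixed(cl$drug)
  p$costs$infusion_month1_dist <- dist_fixed(cm$infusion)
  p$costs$infusion_later_dist <- dist_fixed(cl$infusion)
  for (ae in names(p$adverse_events)) {
    prof <- p$adverse_events[[ae]]
    p$adverse_events[[ae]]$prob_dist <- dist_fixed(prof$monthly_prob)
    p$adverse_events[[ae]]$cost_dist <- dist_fixed(prof$management_cost)
    p$adverse_events[[ae]]$ur_dist <- dist_fixed(prof$utility_reduction)
  }
  p
}

# Zero out every adverse-event probability (for the nesting checks).
no_ae_params <- function(params = default_parameters()) {
  for (ae in names(params$adverse_events))
    params$adverse_events[[ae]]$monthly_prob <- 0
  params
}
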