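# Shared fixtures: the default goat/ractopamine parameterization and a
# few pre-resolved pieces used across tests.  Everything is built in
# code; no stored data.

default_phys <- physio_profile()
default_drug <- drug_params()
default_resolved <- resolve_physiology(default_phys)

# A fast options set for tests that only need moderate accuracy.
fast_opts <- pbpk_options(rtol = 1e-6, atol = 1e-8)

# Construct a minimal rac_timecourse-like object from an explicit
# concentration curve, for testing curve-based operations in isolation.
synthetic_timecourse <- function(times, conc_list, regimen) {
  conc <- do.call(cbind, conc_list)
  structure(list(times = times, conc = conc, regimen = regimen,
                 options = pbpk_options()),
            class = "rac_timecourse")
}
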