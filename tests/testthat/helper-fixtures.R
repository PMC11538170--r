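# Shared fixtures, built once per test run and cached.  Two desk-scale
# grids are used: 40^3 at 5.5 mm (fast unit tests) and 64^3 at 3.44 mm
# (acceptance-scale runs).  Both cover a 220 mm field of view, so the
# phantom's mm-defined anatomy is identical on either grid.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, .fixture_cache))
    assign(name, build(), .fixture_cache)
  get(name, .fixture_cache)
}

grid40 <- list(dim = c(40L, 40L, 40L), spacing = 5.5)
grid64 <- list(dim = c(64L, 64L, 64L), spacing = 3.44)

template_set40 <- function() fixture("tpl40", function()
  phantom_template_pair(n_subjects = 4, seed = 100, spec_args = grid40))

template_set64 <- function() fixture("tpl64", function()
  phantom_template_pair(n_subjects = 8, seed = 100, spec_args = grid64))

# a small random volume for algebraic identities
random_volume <- function(dim = c(12L, 12L, 12L), spacing = 2, seed = 42) {
  set.seed(seed)
  volume(array(stats::rnorm(prod(dim)), dim), spacing = spacing)
}
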