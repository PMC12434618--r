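# Memoized expensive fixtures shared across test files.  Everything is built
# in code at test time; meshes and solves are cached per session.

.fixtures <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fixtures[[name]])) assign(name, builder(), envir = .fixtures)
  .fixtures[[name]]
}

coarse_mesh <- function() fx("coarse_mesh", function() {
  build_mesh(core_shell_geometry(), "coarse")
})

default_mesh <- function() fx("default_mesh", function() {
  build_mesh(core_shell_geometry(), "default")
})

bv_config <- function() scenario_config()

bv_operator_default <- function() fx("bv_operator_default", function() {
  suppressMessages(menpsim:::build_coupled_operator(default_mesh(), bv_config()))
})

# stationary solution at an arbitrary field on the default mesh, cached per H
bv_solution_default <- function(H_T) {
  key <- sprintf("bv_sol_%g", H_T)
  fx(key, function() {
    suppressMessages(stationary_solve(bv_config(), H_T, mesh = default_mesh(),
                                      operator = bv_operator_default()))
  })
}

bv_sweep_default <- function() fx("bv_sweep_default", function() {
  suppressMessages(dc_sweep(bv_config(), mesh = default_mesh()))
})

bv_release_default <- function() fx("bv_release_default", function() {
  suppressMessages(release_study(bv_config(), mesh = default_mesh(),
                                 operator = bv_operator_default()))
})

# zero eigenstrain for a mesh
zero_eigenstrain <- function(mesh) {
  ne <- nrow(mesh$tri)
  list(er = numeric(ne), et = numeric(ne), ez = numeric(ne), grz = numeric(ne))
}
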