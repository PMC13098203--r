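/* Minimal GLPK bridge for flux-balance LPs.
 *
 * Solves   max/min  c'x
 *          s.t.     rlb <= A x <= rub,   clb <= x <= cub
 * with A passed as triplets.  Single-threaded simplex, deterministic.
 */
#include <R.h>
#include <Rinternals.h>
#include <glpk.h>

static int bound_type(double lb, double ub)
{
    int lf = R_FINITE(lb), uf = R_FINITE(ub);
    if (lf && uf) return (lb == ub) ? GLP_FX : GLP_DB;
    if (lf) return GLP_LO;
    if (uf) return GLP_UP;
    return GLP_FR;
}

SEXP sf_glpk_solve(SEXP si, SEXP sj, SEXP sv,
                   SEXP srlb, SEXP srub, SEXP sclb, SEXP scub,
                   SEXP sobj, SEXP smaximize)
{
    int m = LENGTH(srlb), n = LENGTH(sclb), nz = LENGTH(sv);
    int maximize = asLogical(smaximize);
    glp_prob *lp;
    glp_smcp parm;
    SEXP ans, names, xs;
    int k, ret, status;

    glp_term_out(GLP_OFF);
    lp = glp_create_prob();
    glp_set_obj_dir(lp, maximize ? GLP_MAX : GLP_MIN);
    glp_add_rows(lp, m);
    glp_add_cols(lp, n);

    for (k = 0; k < m; k++) {
        double lb = REAL(srlb)[k], ub = REAL(srub)[k];
        glp_set_row_bnds(lp, k + 1, bound_type(lb, ub), lb, ub);
    }
    for (k = 0; k < n; k++) {
        double lb = REAL(sclb)[k], ub = REAL(scub)[k];
        glp_set_col_bnds(lp, k + 1, bound_type(lb, ub), lb, ub);
        glp_set_obj_coef(lp, k + 1, REAL(sobj)[k]);
    }

    {
        /* GLPK uses 1-based arrays with a dummy slot 0 */
        int *ia = (int *) R_alloc(nz + 1, sizeof(int));
        int *ja = (int *) R_alloc(nz + 1, sizeof(int));
        double *ar = (double *) R_alloc(nz + 1, sizeof(double));
        for (k = 0; k < nz; k++) {
            ia[k + 1] = INTEGER(si)[k];
            ja[k + 1] = INTEGER(sj)[k];
            ar[k + 1] = REAL(sv)[k];
        }
        glp_load_matrix(lp, nz, ia, ja, ar);
    }

    glp_init_smcp(&parm);
    parm.msg_lev = GLP_MSG_OFF;
    parm.presolve = GLP_OFF;
    ret = glp_simplex(lp, &parm);
    status = glp_get_status(lp);

    ans = PROTECT(allocVector(VECSXP, 4));
    names = PROTECT(allocVector(STRSXP, 4));
    SET_STRING_ELT(names, 0, mkChar("ret"));
    SET_STRING_ELT(names, 1, mkChar("status"));
    SET_STRING_ELT(names, 2, mkChar("objval"));
    SET_STRING_ELT(names, 3, mkChar("x"));
    setAttrib(ans, R_NamesSymbol, names);

    SET_VECTOR_ELT(ans, 0, ScalarInteger(ret));
    SET_VECTOR_ELT(ans, 1, ScalarInteger(status));
    SET_VECTOR_ELT(ans, 2, ScalarReal(glp_get_obj_val(lp)));
    xs = PROTECT(allocVector(REALSXP, n));
    for (k = 0; k < n; k++) REAL(xs)[k] = glp_get_col_prim(lp, k + 1);
    SET_VECTOR_ELT(ans, 3, xs);

    glp_delete_prob(lp);
    UNPROTECT(3);
    return ans;
}

static const R_CallMethodDef CallEntries[] = {
    {"sf_glpk_solve", (DL_FUNC) &sf_glpk_solve, 9},
    {NULL, NULL, 0}
};

void R_init_strainforge(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
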