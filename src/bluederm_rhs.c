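/* Compiled right-hand side of the 12-compartment keratinocyte model.
 *
 * The R layer resolves everything that is piecewise-constant within an
 * integration segment (blue-light multipliers applied to each rate family,
 * apoptosis rates including the cytotoxic increment) and passes fully
 * effective rates; only the state-dependent pieces (logistic stem niche,
 * transit-amplifying feedback, immune Hill term) are evaluated here.
 *
 * State order: Psc_h, Pta_h, Pga_h, Psp_h, Pgc_h, Pcc_h,
 *              Psc_d, Pta_d, Pga_d, Psp_d, Pgc_d, Pcc_d.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define NPARMS 41

static double parms[NPARMS];

/* parameter layout (see R/simulate.R, segment_parms) */
#define G1HOM   parms[0]
#define K1SHOM  parms[1]
#define K1AHOM  parms[2]
#define G2H     parms[3]
#define K2SH    parms[4]
#define K2AH    parms[5]
#define K3H     parms[6]
#define K4H     parms[7]
#define K5H     parms[8]
#define KM1H    parms[9]
#define KM2H    parms[10]
#define B1H     parms[11]
#define B2H     parms[12]
#define B3H     parms[13]
#define B4H     parms[14]
#define B5H     parms[15]
#define ALPHAH  parms[16]
#define CAP     parms[17]
#define KP      parms[18]
#define KA      parms[19]
#define G1D     parms[20]
#define K1SD    parms[21]
#define K1AD    parms[22]
#define G2D     parms[23]
#define K2SD    parms[24]
#define K2AD    parms[25]
#define K3D     parms[26]
#define K4D     parms[27]
#define K5D     parms[28]
#define KM1D    parms[29]
#define KM2D    parms[30]
#define B1D     parms[31]
#define B2D     parms[32]
#define B3D     parms[33]
#define B4D     parms[34]
#define B5D     parms[35]
#define ALPHAD  parms[36]
#define OMEGA   parms[37]
#define NHILL   parms[38]
#define PTAHOM  parms[39]
#define FLUXCON parms[40]

void bluederm_initmod(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, parms);
}

static void rhs_core(const double *pp, const double *y, double *ydot);

void bluederm_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    rhs_core(parms, y, ydot);
}

/* Direct evaluation entry point (.Call), used to cross-check the R
 * reference implementation without finite-difference noise. */
SEXP bluederm_rhs_eval(SEXP y_, SEXP p_)
{
    if (LENGTH(y_) != 12 || LENGTH(p_) != NPARMS)
        error("bluederm_rhs_eval: bad argument lengths");
    SEXP out = PROTECT(allocVector(REALSXP, 12));
    rhs_core(REAL(p_), REAL(y_), REAL(out));
    UNPROTECT(1);
    return out;
}

static void rhs_core(const double *parms, const double *y, double *ydot)
{
    const int fc = FLUXCON > 0.5;
    const double sgn = fc ? 1.0 : -1.0;
    const double sym2 = fc ? 2.0 : 1.0;

    const double psch = y[0], ptah = y[1], pgah = y[2], psph = y[3],
                 pgch = y[4], pcch = y[5], pscd = y[6], ptad = y[7],
                 pgad = y[8], pspd = y[9], pgcd = y[10], pccd = y[11];

    const double Lg = 1.0 - (psch + pscd) / CAP;
    const double x = (ptah + ptad) / PTAHOM;
    const double threg = OMEGA / (1.0 + (OMEGA - 1.0) * pow(x, NHILL));

    const double g1h = G1HOM * threg;
    const double k1sh = K1SHOM * threg;
    const double k1ah = K1AHOM * threg;

    const double kill = KP * pscd * pscd / (KA * KA + pscd * pscd);

    ydot[0] = (g1h * Lg - k1sh - B1H) * psch + KM1H * ptah;
    ydot[1] = (G2H - K2SH - B2H - KM1H) * ptah +
              sgn * (k1ah + 2.0 * k1sh) * psch + KM2H * pgah;
    ydot[2] = (K2AH + sym2 * K2SH) * ptah - (KM2H + K3H + B3H) * pgah;
    ydot[3] = K3H * pgah - (K4H + B4H) * psph;
    ydot[4] = K4H * psph - (K5H + B5H) * pgch;
    ydot[5] = K5H * pgch - ALPHAH * pcch;

    ydot[6] = (G1D * Lg - K1SD - B1D) * pscd - kill + KM1D * ptad;
    ydot[7] = (G2D - K2SD - B2D - KM1D) * ptad +
              sgn * (K1AD + 2.0 * K1SD) * pscd + KM2D * pgad;
    ydot[8] = (K2AD + sym2 * K2SD) * ptad - (KM2D + K3D + B3D) * pgad;
    /* diseased spinous outflux: k4_d (flux_consistent) or literal k4_h */
    ydot[9] = K3D * pgad - ((fc ? K4D : K4H) + B4D) * pspd;
    ydot[10] = 0.0;
    /* parakeratosis: spinous cells cornify directly (flux_consistent);
       as printed the influx comes from the identically-zero granular pool */
    ydot[11] = (fc ? K4D * pspd : K5D * pgcd) - ALPHAD * pccd;
}

static const R_CMethodDef cMethods[] = {
    {"bluederm_initmod", (DL_FUNC) &bluederm_initmod, 1},
    {"bluederm_derivs",  (DL_FUNC) &bluederm_derivs,  6},
    {NULL, NULL, 0}
};

static const R_CallMethodDef callMethods[] = {
    {"bluederm_rhs_eval", (DL_FUNC) &bluederm_rhs_eval, 2},
    {NULL, NULL, 0}
};

void R_init_bluederm(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, callMethods, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
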