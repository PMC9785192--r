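/* Whole-body PBPK right-hand side for one or two compounds coupled by
 * competitive CYP3A4 inhibition, with a 5-segment gastrointestinal
 * lumen (undissolved-in-formulation / solid / dissolved pools per
 * segment), Weibull or particle dissolution, meal-dependent gastric
 * emptying, and cumulative elimination accumulators for the
 * mass-balance ledger.
 *
 * Layout contracts (mirrored by R/engine-parms.R):
 *   time unit: hours; systemic amounts: umol; lumen masses: mg.
 */

#include <R.h>
#include <math.h>

#define NORG   14   /* perfusion organs */
#define NCOMP  16   /* + arterial(14), venous(15) */
#define NSEG   5
#define MAXD   64
#define MAXM   40

/* organ indices */
#define O_LUNG 0
#define O_KIDNEY 5
#define O_SPLEEN 10
#define O_STWALL 11
#define O_GUT  12
#define O_LIVER 13
#define I_ART  14
#define I_VEN  15

/* per-compound state offsets */
#define NSTATE_C 39
#define SU(s)  (16 + (s))        /* undissolved in formulation */
#define SS(s)  (21 + (s))        /* solid (particles/precipitate) */
#define SD(s)  (26 + (s))        /* dissolved */
#define A_3A4  31
#define A_2C9  32
#define A_UGT  33
#define A_G3A4 34
#define A_REN  35
#define A_BIL  36
#define A_OUT  37                /* transited out of colon, mg */
#define A_ABS  38                /* cumulative absorbed, mg */

/* global parameter indices */
#define P_NACT   0
#define P_MIN    1
#define P_IDRV   2
#define P_GFR    3
#define P_V      4               /* V[16] */
#define P_Q      20              /* Q[14]  (Q[0] = cardiac output) */
#define P_GIV    34              /* Vg[5], L */
#define P_GIA    39              /* Ag[5], cm2 */
#define P_GIK    44              /* ktr[5], 1/h */
#define P_NMEAL  49
#define P_TAUM   50
#define P_TMEAL  51              /* [MAXM] */
#define P_AMEAL  91              /* [MAXM] */
#define P_CBASE  131

/* per-compound parameter offsets */
#define CPLEN    169
#define C_ACT    0
#define C_MW     1
#define C_FU     2
#define C_ROUTE  3               /* 0 iv, 1 oral */
#define C_KP     4               /* [14] */
#define C_K3A4   18
#define C_K2C9   19
#define C_KUGT   20
#define C_KG3A4  21
#define C_KBIL   22
#define C_FGFR   23
#define C_KI     24
#define C_INHIB  25
#define C_PEFF   26              /* cm/h */
#define C_FKIND  27              /* 0 iv, 1 solution, 2 weibull, 3 particle */
#define C_T50    28
#define C_SHAPE  29
#define C_LAG    30
#define C_GBLOCK 31
#define C_KPREC  32
#define C_KDISS  33              /* mL/mg/h */
#define C_CS     34              /* [5], mg/mL */
#define C_NDOSE  39
#define C_IDUR   40
#define C_TDOSE  41              /* [MAXD] */
#define C_ADOSE  105             /* [MAXD] */

#define NPARMS (P_CBASE + 2 * CPLEN)

static double parms[NPARMS];

void pbpk_init(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, parms);
}

static double meal_mult(double t)
{
    int n = (int) parms[P_NMEAL];
    double tau = parms[P_TAUM];
    double m = 1.0;
    for (int i = 0; i < n; i++) {
        double tm = parms[P_TMEAL + i];
        if (t > tm)
            m += parms[P_AMEAL + i] * exp(-(t - tm) / tau);
    }
    return m;
}

/* Weibull release hazard based on time since most recent dose */
static double release_hazard(const double *cp, double t)
{
    int nd = (int) cp[C_NDOSE];
    double tlast = -1.0;
    for (int i = 0; i < nd; i++) {
        double td = cp[C_TDOSE + i];
        if (td <= t && td > tlast && cp[C_ADOSE + i] > 0)
            tlast = td;
    }
    if (tlast < 0) return 0.0;
    double te = t - tlast - cp[C_LAG];
    if (te <= 0) return 0.0;
    double t50 = cp[C_T50], sh = cp[C_SHAPE];
    return M_LN2 * sh * pow(te, sh - 1.0) / pow(t50, sh);
}

static double infusion_rate_umol(const double *cp, double t)
{
    if (cp[C_ROUTE] != 0.0) return 0.0;
    double dur = cp[C_IDUR];
    if (dur <= 0) return 0.0;      /* bolus handled as state event */
    int nd = (int) cp[C_NDOSE];
    double rate = 0.0;
    for (int i = 0; i < nd; i++) {
        double td = cp[C_TDOSE + i];
        if (t >= td && t < td + dur)
            rate += cp[C_ADOSE + i] * 1000.0 / cp[C_MW] / dur;
    }
    return rate;
}

void pbpk_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    const double *V = parms + P_V;
    const double *Q = parms + P_Q;
    double tt = *t;
    int nact = (int) parms[P_NACT];
    int minimal = (int) parms[P_MIN];
    int idrv = (int) parms[P_IDRV];

    for (int i = 0; i < 2 * NSTATE_C; i++) ydot[i] = 0.0;

    for (int c = 0; c < 2; c++) {
        const double *cp = parms + P_CBASE + c * CPLEN;
        if (c >= nact || cp[C_ACT] == 0.0) continue;
        double *yc = y + c * NSTATE_C;
        double *dc = ydot + c * NSTATE_C;
        double fu = cp[C_FU];
        double mw = cp[C_MW];

        /* competitive CYP3A4 inhibition by the other compound */
        double fac_li = 1.0, fac_gut = 1.0;
        if (cp[C_INHIB] != 0.0) {
            int q = 1 - c;
            const double *qp = parms + P_CBASE + q * CPLEN;
            if (q < nact && qp[C_ACT] != 0.0 && qp[C_KI] > 0.0) {
                const double *yq = y + q * NSTATE_C;
                double iu_li, iu_gut;
                if (idrv == 0 && !minimal) {
                    iu_li  = qp[C_FU] * yq[O_LIVER] /
                             (V[O_LIVER] * qp[C_KP + O_LIVER]);
                    iu_gut = qp[C_FU] * yq[O_GUT] /
                             (V[O_GUT] * qp[C_KP + O_GUT]);
                } else {
                    iu_li = iu_gut = qp[C_FU] * yq[I_VEN] / V[I_VEN];
                }
                fac_li  = 1.0 / (1.0 + iu_li  / qp[C_KI]);
                fac_gut = 1.0 / (1.0 + iu_gut / qp[C_KI]);
            }
        }

        if (minimal) {
            /* single well-stirred compartment (venous blood volume) */
            double ven = yc[I_VEN];
            double v3a4 = cp[C_K3A4] * fac_li * fu * ven;
            double v2c9 = cp[C_K2C9] * fu * ven;
            double vugt = cp[C_KUGT] * fu * ven;
            double vbil = cp[C_KBIL] * fu * ven;
            double vren = cp[C_FGFR] * parms[P_GFR] * fu * ven / V[I_VEN];
            dc[I_VEN] = infusion_rate_umol(cp, tt)
                        - v3a4 - v2c9 - vugt - vbil - vren;
            dc[A_3A4] = v3a4; dc[A_2C9] = v2c9; dc[A_UGT] = vugt;
            dc[A_BIL] = vbil; dc[A_REN] = vren;
            continue;
        }

        double c_art = yc[I_ART] / V[I_ART];
        double c_ven = yc[I_VEN] / V[I_VEN];
        /* venous-equilibrated plasma concentration leaving organ i */
        double cv[NORG];
        for (int i = 0; i < NORG; i++)
            cv[i] = yc[i] / (V[i] * cp[C_KP + i]);

        /* lung (receives total venous return) */
        dc[O_LUNG] = Q[0] * (c_ven - cv[O_LUNG]);
        /* arterial pool */
        dc[I_ART] = Q[0] * (cv[O_LUNG] - c_art);

        double ven_in = 0.0;
        for (int i = 1; i < NORG; i++) {
            if (i == O_SPLEEN || i == O_STWALL || i == O_GUT ||
                i == O_LIVER) continue;
            dc[i] = Q[i] * (c_art - cv[i]);
            ven_in += Q[i] * cv[i];
        }

        /* renal filtration of arterial plasma water */
        double vren = cp[C_FGFR] * parms[P_GFR] * fu * c_art;
        dc[O_KIDNEY] -= vren;
        dc[A_REN] = vren;

        /* splanchnic organs -> portal vein -> liver */
        dc[O_SPLEEN] = Q[O_SPLEEN] * (c_art - cv[O_SPLEEN]);
        dc[O_STWALL] = Q[O_STWALL] * (c_art - cv[O_STWALL]);

        /* gut wall: perfusion + luminal absorption + mucosal CYP3A4 */
        double abs_mg = 0.0;
        if (cp[C_ROUTE] == 1.0) {
            double hz = release_hazard(cp, tt);
            double ksto = (parms + P_GIK)[0] / meal_mult(tt);
            double inU = 0.0, inS = 0.0, inD = 0.0;
            for (int s = 0; s < NSEG; s++) {
                double ks = (s == 0) ? ksto : (parms + P_GIK)[s];
                double vg_mL = (parms + P_GIV)[s] * 1000.0;
                double cs = cp[C_CS + s];
                double conc = yc[SD(s)] / vg_mL;
                double rel = 0.0;
                if (cp[C_FKIND] == 2.0 &&
                    !(s == 0 && cp[C_GBLOCK] != 0.0))
                    rel = hz * yc[SU(s)];
                double diss = 0.0;
                if (conc < cs && yc[SS(s)] > 0)
                    diss = cp[C_KDISS] * yc[SS(s)] * (cs - conc);
                double prec = 0.0;
                double exc = yc[SD(s)] - cs * vg_mL;
                if (exc > 0) prec = cp[C_KPREC] * exc;
                double absr = cp[C_PEFF] * (parms + P_GIA)[s] *
                              (yc[SD(s)] / vg_mL);
                dc[SU(s)] = inU - ks * yc[SU(s)] - rel;
                dc[SS(s)] = inS - ks * yc[SS(s)] + prec - diss;
                dc[SD(s)] = inD - ks * yc[SD(s)] + rel + diss - prec - absr;
                abs_mg += absr;
                if (s < NSEG - 1) {
                    inU = ks * yc[SU(s)];
                    inS = ks * yc[SS(s)];
                    inD = ks * yc[SD(s)];
                } else {
                    dc[A_OUT] = ks * (yc[SU(s)] + yc[SS(s)] + yc[SD(s)]);
                }
            }
            dc[A_ABS] = abs_mg;
        }
        double abs_umol = abs_mg * 1000.0 / mw;
        double vg3a4 = cp[C_KG3A4] * fac_gut * fu * yc[O_GUT] /
                       cp[C_KP + O_GUT];
        dc[O_GUT] = Q[O_GUT] * (c_art - cv[O_GUT]) + abs_umol - vg3a4;
        dc[A_G3A4] = vg3a4;

        /* liver: hepatic artery + portal inflow, metabolism, bile */
        double q_li = Q[O_LIVER] + Q[O_SPLEEN] + Q[O_STWALL] + Q[O_GUT];
        double v3a4 = cp[C_K3A4] * fac_li * fu * yc[O_LIVER] /
                      cp[C_KP + O_LIVER];
        double v2c9 = cp[C_K2C9] * fu * yc[O_LIVER] / cp[C_KP + O_LIVER];
        double vugt = cp[C_KUGT] * fu * yc[O_LIVER] / cp[C_KP + O_LIVER];
        double vbil = cp[C_KBIL] * fu * yc[O_LIVER] / cp[C_KP + O_LIVER];
        dc[O_LIVER] = Q[O_LIVER] * c_art + Q[O_SPLEEN] * cv[O_SPLEEN] +
                      Q[O_STWALL] * cv[O_STWALL] + Q[O_GUT] * cv[O_GUT] -
                      q_li * cv[O_LIVER] - v3a4 - v2c9 - vugt - vbil;
        dc[A_3A4] = v3a4; dc[A_2C9] = v2c9; dc[A_UGT] = vugt;
        dc[A_BIL] = vbil;

        /* venous pool */
        dc[I_VEN] = ven_in + q_li * cv[O_LIVER] - Q[0] * c_ven +
                    infusion_rate_umol(cp, tt);
    }
}
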